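# Independent brute-force oracles, kept deliberately separate from the
# package's own code paths.

# Exact HWE test by direct enumeration: exact probability of each attainable
# heterozygote count given n and the allele count, from multinomial
# arrangement counting (choose() products), then the mass-based p-value.
hweOracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa
    hets <- seq.int(nA %% 2, min(nA, 2 * n - nA), by = 2)
    w <- vapply(hets, function(h) {
        aa <- (nA - h) / 2
        choose(n, aa) * choose(n - aa, h) * 2^h
    }, numeric(1))
    probs <- w / sum(w)
    pobs <- probs[hets == nAa]
    sum(probs[probs <= pobs * (1 + 1e-9)])
}

# Two-sided Fisher p by hypergeometric enumeration over all tables with the
# observed margins.
fisherOracle <- function(tab) {
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    as <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- dhyper(as, c1, n - c1, r1)
    pobs <- dhyper(tab[1, 1], c1, n - c1, r1)
    sum(probs[probs <= pobs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values into groups of sizes n1/n2; U uses the win/tie kernel.
mwUStat <- function(x, y) {
    sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}
mwOracle <- function(x, y) {
    pooled <- c(x, y)
    n1 <- length(x)
    mu <- n1 * length(y) / 2
    uobs <- mwUStat(x, y)
    idx <- utils::combn(length(pooled), n1)
    us <- apply(idx, 2, function(i) mwUStat(pooled[i], pooled[-i]))
    mean(abs(us - mu) >= abs(uobs - mu) - 1e-9)
}

# Fast rank-based AUC used by the bootstrap oracle (midranks handle ties
# with the half kernel).
aucRank <- function(scores, status) {
    r <- rank(scores)
    n1 <- sum(status == 1)
    n0 <- sum(status == 0)
    (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified bootstrap SE of the AUC.
bootAucSE <- function(scores, status, B = 2000) {
    ci <- which(status == 1)
    co <- which(status == 0)
    reps <- vapply(seq_len(B), function(b) {
        i <- c(sample(ci, replace = TRUE), sample(co, replace = TRUE))
        aucRank(scores[i], status[i])
    }, numeric(1))
    sd(reps)
}
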