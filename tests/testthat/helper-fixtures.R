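# Shared fixture builders; everything is generated in code, seeded.

randomTrain <- function(n, p, seed, nonneg = TRUE) {
    set.seed(seed)
    v <- matrix(rnorm(n * p), n, p)
    if (nonneg) v <- abs(v)
    ExpressionMatrix(v, sampleIds = paste0("s", seq_len(n)),
                     featureIds = paste0("f", seq_len(p)))
}

randomMaskedProfile <- function(p, nMissing, seed, nonneg = TRUE) {
    set.seed(seed + 1000L)
    v <- rnorm(p)
    if (nonneg) v <- abs(v)
    mask <- rep(FALSE, p)
    if (nMissing > 0L) mask[sample.int(p, nMissing)] <- TRUE
    v[mask] <- NA
    MaskedProfile(v, mask = mask, sampleId = paste0("t", seed))
}

# small labelled data set on which the softmax classifier is near-perfect
toyClassificationData <- function(n = 60, seed = 1) {
    set.seed(seed)
    cls <- rep(c("a", "b"), length.out = n)
    shift <- ifelse(cls == "b", 3, 0)
    v <- cbind(rnorm(n) + shift, rnorm(n) - shift, matrix(rnorm(n * 3), n))
    ExpressionMatrix(v, sampleIds = paste0("s", seq_len(n)),
                     featureIds = paste0("f", 1:5), labels = cls)
}
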