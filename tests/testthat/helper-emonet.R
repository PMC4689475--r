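# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# a small report set from a reports-by-emotions matrix; unnamed matrices are
# padded with zero columns up to the full taxonomy
makeReports <- function(ind, pid = NULL, hours = NULL, gender = NULL,
                        tax = emotionTaxonomy()) {
    emo <- emotions(tax)
    if (is.null(colnames(ind)))
        stop("makeReports needs named indicator columns")
    full <- matrix(0L, nrow(ind), length(emo), dimnames = list(NULL, emo))
    full[, colnames(ind)] <- as.integer(ind)
    n <- nrow(full)
    if (is.null(pid)) pid <- sprintf("p%03d", seq_len(n))
    if (is.null(hours)) hours <- rep(12, n)
    ts <- as.POSIXct("2013-03-04 00:00:00", tz = "UTC") +
        hours * 3600 + seq_len(n)  # distinct seconds, Monday
    EmotionReportSet(full, pid, ts, gender, tax)
}

# 2-positive / 2-negative toy taxonomy used by the typology examples
tax4 <- function() emotionTaxonomy(positive = c("A", "B"),
                                   negative = c("C", "D"))

# independent oracle: phi from the 2x2 contingency table
phi2x2 <- function(a, b) {
    n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
    n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
    den <- sqrt((n11 + n10)) * sqrt((n01 + n00)) *
           sqrt((n11 + n01)) * sqrt((n10 + n00))
    if (den == 0) return(NA_real_)
    (n11 * n00 - n10 * n01) / den
}

# independent oracle: degree centrality by an explicit double loop
dcDoubleLoop <- function(W) {
    k <- nrow(W)
    out <- numeric(k)
    for (i in seq_len(k)) for (j in seq_len(k))
        if (i != j) out[i] <- out[i] + abs(W[i, j])
    setNames(out, rownames(W))
}

# random small report set (for property-style loops)
randomReports <- function(n = 20, p = 0.3, tax = emotionTaxonomy()) {
    emo <- emotions(tax)
    ind <- matrix(rbinom(n * length(emo), 1L, p), n,
                  dimnames = list(NULL, emo))
    makeReports(ind, pid = sprintf("p%02d", sample(5, n, TRUE)),
                hours = sample(6:22, n, TRUE), tax = tax)
}
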