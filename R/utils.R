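# Shared internal state: per-session caches for the molecule library and
# Morgan fingerprints (OpenBabel fingerprinting dominates runtime otherwise).
.pkgEnv <- new.env(parent = emptyenv())
.pkgEnv$fpCache <- new.env(parent = emptyenv())

#' Clear the session fingerprint cache
#'
#' Fingerprints are memoised per canonical SMILES for the lifetime of the R
#' session. This drops the cache (mainly useful in long sessions).
#'
#' @return Invisibly, the number of entries removed.
#' @export
clearFingerprintCache <- function() {
    n <- length(ls(.pkgEnv$fpCache))
    .pkgEnv$fpCache <- new.env(parent = emptyenv())
    invisible(n)
}

# Derive a child seed from a master seed and one or two indices; kept well
# below 2^31 so set.seed() always accepts it.
.deriveSeed <- function(seed, i, j = 0L) {
    as.integer((as.numeric(seed) * 7919 + i * 131 + j) %% 2147483629)
}
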