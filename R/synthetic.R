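# Synthetic-data generator: a deterministic fragment-combination library
# (ring cores x acyclic substituents) yields valid, diverse molecules with
# controllable scaffold families; planted linear structure-activity signal
# over fingerprint bits plus Gaussian noise gives assay-level ligand sets
# with known ground truth, and labelled active/inactive sets emulate the
# CLASS benchmark construction.

# Ring cores. Each entry: a one-slot and a two-slot SMILES template plus a
# family label; families are chosen so that distinct families have
# distinct cyclic skeletons (heteroatom changes alone would not).
.cores <- list(
    list(family = "benzene",     t1 = "c1ccc(%s)cc1",
         t2 = "c1cc(%s)cc(%s)c1",  csk = "C1CCCCC1"),
    list(family = "pyridine",    t1 = "c1ccnc(%s)c1",
         t2 = "c1cc(%s)cnc1%s",    csk = "C1CCCCC1"),
    list(family = "thiophene",   t1 = "c1csc(%s)c1",
         t2 = "c1sc(%s)cc1%s",     csk = "C1CCCC1"),
    list(family = "naphthalene", t1 = "c1ccc2cc(%s)ccc2c1",
         t2 = "c1cc(%s)c2cc(%s)ccc2c1", csk = "C1CCC2C(C1)CCCC2"),
    list(family = "biphenyl",    t1 = "c1ccc(cc1)c1ccc(%s)cc1",
         t2 = "c1cc(%s)ccc1c1ccc(%s)cc1",
         csk = "C1CCC(CC1)C1CCCCC1"),
    list(family = "benzofuran",  t1 = "c1ccc2c(c1)cc(%s)o2",
         t2 = "c1cc2c(cc1%s)cc(%s)o2", csk = "C1CCC2C(C1)CCC2"),
    list(family = "cycloheptane", t1 = "C1CCCC(%s)CC1",
         t2 = "C1CC(%s)CCC(%s)C1", csk = "C1CCCCCC1"),
    list(family = "indane",      t1 = "c1ccc2c(c1)CCC2%s",
         t2 = "c1cc2c(cc1%s)CCC2%s", csk = "C1CCC2C(C1)CCC2"))

.substituents <- c("C", "CC", "CCC", "C(C)C", "O", "OC", "OCC", "N",
                   "NC", "N(C)C", "F", "Cl", "Br", "C#N", "C(=O)O",
                   "C(=O)N", "C(=O)C", "CO", "CN", "CCO", "S", "SC",
                   "C(F)(F)F", "CC#N", "OC(=O)C")

# Substituent sets used to plant a scaffold-independent activity signal in
# class sets: actives preferentially carry "signal" groups.
.signalSubs <- c("C(=O)N", "C#N", "N(C)C", "CCO", "OC(=O)C", "CC#N")

#' The built-in synthetic molecule library
#'
#' Deterministic enumeration over a fragment grammar: eight ring cores
#' (with distinct cyclic skeletons across the seven distinct families)
#' combined with up to two acyclic substituents from a fixed list. All
#' SMILES are valid by construction and canonicalized on first use; the
#' library is cached for the session.
#'
#' @param twoSlot also enumerate doubly-substituted variants (default
#'   TRUE; ~5400 molecules, or ~200 without).
#' @return data.frame with columns \code{smiles} (canonical),
#'   \code{family}, \code{coreCsk} (the family's expected cyclic
#'   skeleton), \code{sub1}, \code{sub2} (\code{NA} when absent).
#' @export
moleculeLibrary <- function(twoSlot = TRUE) {
    key <- paste0("library_", twoSlot)
    if (!is.null(.pkgEnv[[key]])) return(.pkgEnv[[key]])
    rows <- list()
    for (co in .cores) {
        rows[[length(rows) + 1L]] <- data.frame(
            smiles = sprintf(co$t1, .substituents), family = co$family,
            coreCsk = co$csk, sub1 = .substituents, sub2 = NA_character_,
            stringsAsFactors = FALSE)
        if (twoSlot) {
            # unordered substituent pairs, enumerated by index so the
            # selection is locale-independent (string collation is not)
            grid <- expand.grid(i = seq_along(.substituents),
                                j = seq_along(.substituents))
            grid <- grid[grid$i < grid$j, ]
            grid <- data.frame(s1 = .substituents[grid$i],
                               s2 = .substituents[grid$j],
                               stringsAsFactors = FALSE)
            rows[[length(rows) + 1L]] <- data.frame(
                smiles = sprintf(co$t2, grid$s1, grid$s2),
                family = co$family, coreCsk = co$csk,
                sub1 = grid$s1, sub2 = grid$s2, stringsAsFactors = FALSE)
        }
    }
    lib <- do.call(rbind, rows)
    # canonicalize (batch; all strings are valid by construction) and drop
    # any accidental duplicates
    can <- suppressWarnings(ChemmineOB::convertFormat(
        "SMI", "CAN", paste(lib$smiles, collapse = "\n")))
    can <- vapply(strsplit(can, "\n")[[1L]],
                  function(s) strsplit(s, "\t")[[1L]][1L], "",
                  USE.NAMES = FALSE)
    if (length(can) != nrow(lib))
        stop("internal: library enumeration produced invalid SMILES")
    lib$smiles <- can
    lib <- lib[!duplicated(lib$smiles), , drop = FALSE]
    rownames(lib) <- NULL
    .pkgEnv[[key]] <- lib
    lib
}

#' Generate a synthetic assay ligand set with planted signal
#'
#' Samples molecules from the built-in library and assigns
#' \eqn{activity = offset + X w + N(0, \sigma)} where \eqn{X} are the
#' molecules' Morgan fingerprint bits and \eqn{w} is a sparse weight
#' vector over \code{nSignalBits} informative bits (bits with library
#' prevalence between 10\% and 90\%, so the signal is learnable).
#' Activities are clipped to [3, 11], mimicking realistic potency ranges.
#' Deterministic per seed.
#'
#' @param nCompounds number of compounds (must not exceed the library).
#' @param nSignalBits number of informative fingerprint bits.
#' @param noiseSigma Gaussian noise SD (-log10 M units).
#' @param activityOffset baseline activity (default 6).
#' @param weightRange absolute weight range; signs are random.
#' @param assayId identifier for the emitted set.
#' @param seed integer seed.
#' @param library optional molecule library data.frame.
#' @return A \code{\linkS4class{LigandSet}} whose \code{metadata} records
#'   the planted signal (\code{signalBits}, \code{weights},
#'   \code{noiseSigma}, \code{offset}).
#' @export
generateLigandSet <- function(nCompounds = 200L, nSignalBits = 12L,
                              noiseSigma = 0.3, activityOffset = 6,
                              weightRange = c(0.3, 1.0),
                              assayId = "SYNTH-1", seed = 1L,
                              library = NULL) {
    lib <- library %||% moleculeLibrary()
    if (nCompounds > nrow(lib))
        stop("requested ", nCompounds, " compounds but the library holds ",
             nrow(lib))
    set.seed(as.integer(seed))
    pick <- sample.int(nrow(lib), nCompounds)
    smi <- lib$smiles[pick]
    ids <- sprintf("CPD%05d", pick)
    mols <- new("MoleculeSet", smiles = smi, molId = ids,
                atomCount = rep(1L, nCompounds),
                ringFlag = rep(TRUE, nCompounds))
    X <- morganFingerprint(mols)
    prev <- colMeans(X)
    eligible <- which(prev >= 0.1 & prev <= 0.9)
    if (length(eligible) < nSignalBits)
        stop("not enough informative bits for the requested signal")
    bits <- sort(sample(eligible, nSignalBits))
    w <- runif(nSignalBits, weightRange[1L], weightRange[2L]) *
        sample(c(-1, 1), nSignalBits, replace = TRUE)
    activity <- activityOffset + as.numeric(X[, bits] %*% w) +
        rnorm(nCompounds, 0, noiseSigma)
    activity <- pmin(pmax(activity, 3), 11)
    new("LigandSet", assayId = assayId, compoundId = ids, smiles = smi,
        activity = activity,
        metadata = list(signalBits = bits, weights = w,
                        noiseSigma = noiseSigma,
                        offset = activityOffset, seed = seed))
}

#' Generate a raw activity table across several synthetic assays
#'
#' Produces the delimited-record form consumed by the curation module,
#' including a controllable sprinkling of records the filters must remove
#' (censored relations, low confidence) and replicate measurements for
#' the aggregator.
#'
#' @param nAssays number of assays.
#' @param nCompounds compounds per assay.
#' @param noiseSigma per-assay activity noise.
#' @param dirtyFraction fraction of extra records carrying a censored
#'   relation or an off-policy confidence score.
#' @param replicateFraction fraction of compounds receiving a duplicate
#'   measurement (small jitter, below the aggregation cutoff).
#' @param seed integer seed.
#' @return data.frame of activity records.
#' @export
generateActivityTable <- function(nAssays = 5L, nCompounds = 120L,
                                  noiseSigma = 0.2, dirtyFraction = 0.05,
                                  replicateFraction = 0.05, seed = 1L) {
    recs <- list()
    for (a in seq_len(nAssays)) {
        ls <- generateLigandSet(nCompounds = nCompounds,
                                noiseSigma = noiseSigma,
                                assayId = sprintf("ASSAY-%03d", a),
                                seed = .deriveSeed(seed, a))
        df <- data.frame(compoundId = ls@compoundId, smiles = ls@smiles,
                         assayId = ls@assayId,
                         activityType = sample(c("IC50", "Ki"),
                                               length(ls), TRUE),
                         relation = "=", value = ls@activity,
                         confidence = sample(c(7L, 9L), length(ls), TRUE),
                         stringsAsFactors = FALSE)
        set.seed(.deriveSeed(seed, a, 1L))
        nRep <- round(replicateFraction * nrow(df))
        if (nRep > 0L) {
            dup <- df[sample.int(nrow(df), nRep), , drop = FALSE]
            dup$value <- dup$value + runif(nRep, -0.2, 0.2)
            df <- rbind(df, dup)
        }
        nDirty <- round(dirtyFraction * nrow(df))
        if (nDirty > 0L) {
            dirty <- df[sample.int(nrow(df), nDirty), , drop = FALSE]
            half <- seq_len(nDirty) %% 2L == 0L
            dirty$relation[half] <- ">"
            dirty$confidence[!half] <- 8L
            df <- rbind(df, dirty)
        }
        recs[[a]] <- df
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
}

#' Generate a CLASS-style benchmark set with planted scaffold families
#'
#' Actives are drawn from \code{nScaffolds} distinct cyclic-skeleton
#' families, the first of which always holds at least five members (a
#' guaranteed RACSK); inactives are drawn across all families. A
#' structure-activity signal is planted through the substituents: a
#' fraction \code{hopSignal} of actives carry groups from a fixed signal
#' set, inactives carry background groups, so a classifier can generalize
#' activity across scaffolds. Activities respect the CLASS labelling rule
#' (inactive <= 5, active >= 6; the gap in between stays empty). The
#' metadata manifest records each compound's true CSK family for oracle
#' checks.
#'
#' @param nAct,nInact class sizes.
#' @param nScaffolds number of active scaffold families (2..7).
#' @param hopSignal fraction of actives carrying signal substituents.
#' @param targetId identifier.
#' @param seed integer seed.
#' @return A \code{\linkS4class{BenchSet}} of kind \code{"CLASS"}.
#' @export
generateClassSet <- function(nAct = 80L, nInact = 120L, nScaffolds = 4L,
                             hopSignal = 0.9, targetId = "CLASS-1",
                             seed = 1L) {
    if (nScaffolds < 2L) stop("need at least 2 scaffold families")
    lib <- moleculeLibrary()
    families <- unique(lib$family[!duplicated(lib$coreCsk)])
    fams <- unique(lib[, c("family", "coreCsk")])
    fams <- fams[!duplicated(fams$coreCsk), ]
    if (nScaffolds > nrow(fams))
        stop("at most ", nrow(fams), " distinct-CSK families available")
    set.seed(as.integer(seed))
    famPick <- fams$family[seq_len(nScaffolds)]
    hasSignal <- !is.na(lib$sub1) &
        (lib$sub1 %in% .signalSubs |
         (!is.na(lib$sub2) & lib$sub2 %in% .signalSubs))
    # active family sizes: first family takes half (>= 5), rest share the
    # remainder roughly evenly
    sizes <- rep(0L, nScaffolds)
    sizes[1L] <- max(5L, ceiling(nAct / 2))
    rest <- nAct - sizes[1L]
    if (nScaffolds > 1L) {
        per <- rest %/% (nScaffolds - 1L)
        sizes[-1L] <- per
        sizes[2L] <- sizes[2L] + rest - per * (nScaffolds - 1L)
    }
    takenRows <- integer(0)
    drawFrom <- function(rows, nWant) {
        rows <- setdiff(rows, takenRows)
        if (length(rows) < nWant)
            stop("infeasible counts: library family exhausted")
        sel <- sample(rows, nWant)
        takenRows <<- c(takenRows, sel)
        sel
    }
    actRows <- integer(0); actFam <- character(0)
    for (f in seq_len(nScaffolds)) {
        if (sizes[f] == 0L) next
        famRows <- which(lib$family == famPick[f])
        nSig <- round(hopSignal * sizes[f])
        sel <- c(drawFrom(intersect(famRows, which(hasSignal)), nSig),
                 drawFrom(intersect(famRows, which(!hasSignal)),
                          sizes[f] - nSig))
        actRows <- c(actRows, sel)
        actFam <- c(actFam, rep(famPick[f], sizes[f]))
    }
    inaRows <- drawFrom(which(!hasSignal), nInact)
    actSmi <- lib$smiles[actRows]; inaSmi <- lib$smiles[inaRows]
    activity <- c(runif(length(actRows), 6.2, 9.0),
                  runif(length(inaRows), 3.2, 4.8))
    benchSet(targetId, actSmi, inaSmi, kind = "CLASS",
             activity = activity,
             metadata = list(
                 family = c(actFam, lib$family[inaRows]),
                 coreCsk = lib$coreCsk[c(actRows, inaRows)],
                 familySizes = setNames(sizes, famPick),
                 hopSignal = hopSignal, seed = seed))
}
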