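# Molecule parsing, Morgan fingerprint encoding and scaffold derivation.
# OpenBabel (via ChemmineOB) does the heavy lifting for SMILES
# canonicalization, graph extraction and circular-fingerprint hashing;
# Bemis-Murcko scaffold pruning and the cyclic-skeleton reduction are
# implemented here on the heavy-atom graph.

# Canonicalize one SMILES; NA when OpenBabel cannot parse it. Output lines
# look like "CCO\t<title>\n".
.obCanonical <- function(smi) {
    out <- tryCatch(
        suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smi)),
        error = function(e) "")
    out <- strsplit(out, "[\t\n]")[[1L]]
    if (length(out) == 0L || !nzchar(out[1L])) NA_character_ else out[1L]
}

# Heavy-atom graphs (element vector + bond matrix with columns a1, a2,
# order) extracted from OpenBabel's kekulized, implicit-hydrogen SDF
# output. The V2000 connection table is fixed-width, so the atom and bond
# blocks are sliced directly; input must already be canonical/parseable.
.molGraphFromV2000 <- function(lines) {
    ci <- grep("V2000", lines, fixed = TRUE)[1L]
    counts <- lines[ci]
    nAtoms <- as.integer(substr(counts, 1L, 3L))
    nBonds <- as.integer(substr(counts, 4L, 6L))
    elem <- character(nAtoms)
    for (i in seq_len(nAtoms))
        elem[i] <- trimws(substr(lines[ci + i], 32L, 34L))
    bonds <- matrix(integer(0), ncol = 3L,
                    dimnames = list(NULL, c("a1", "a2", "order")))
    if (nBonds > 0L) {
        bl <- lines[ci + nAtoms + seq_len(nBonds)]
        bonds <- cbind(a1 = as.integer(substr(bl, 1L, 3L)),
                       a2 = as.integer(substr(bl, 4L, 6L)),
                       order = as.integer(substr(bl, 7L, 9L)))
    }
    list(elem = elem, bonds = bonds)
}

.parseGraphs <- function(canonical) {
    sdftxt <- suppressWarnings(
        ChemmineOB::convertFormat("SMI", "SDF",
                                  paste(canonical, collapse = "\n")))
    recs <- strsplit(sdftxt, "\\$\\$\\$\\$\n?")[[1L]]
    recs <- recs[vapply(recs, function(r) grepl("V2000", r), TRUE)]
    if (length(recs) != length(canonical))
        stop("internal: molecule count changed during SDF conversion")
    lapply(recs, function(r) .molGraphFromV2000(strsplit(r, "\n")[[1L]]))
}

#' Parse and canonicalize molecules
#'
#' Parses SMILES with OpenBabel, keeps the largest covalent fragment of
#' multi-fragment inputs (with a warning; inputs are expected to be
#' pre-standardized, so this is a minimal salt-stripping stand-in), and
#' returns canonical SMILES together with heavy-atom counts and ring flags.
#' Canonicalization is idempotent: re-parsing the canonical form returns
#' the same string.
#'
#' @param smiles character vector of SMILES.
#' @param ids optional molecule identifiers (default: the canonical SMILES).
#' @return A \code{\linkS4class{MoleculeSet}}.
#' @examples
#' mols <- parseMolecules(c("CCO", "c1ccccc1"))
#' atomCount(mols)  # 3, 6
#' @export
parseMolecules <- function(smiles, ids = NULL) {
    stopifnot(is.character(smiles), length(smiles) > 0L)
    if (any(!nzchar(smiles)))
        stop("empty SMILES at position ",
             which(!nzchar(smiles))[1L])
    stripped <- FALSE
    canonical <- vapply(seq_along(smiles), function(i) {
        s <- smiles[i]
        frags <- strsplit(s, ".", fixed = TRUE)[[1L]]
        frags <- frags[nzchar(frags)]
        if (length(frags) > 1L) {
            can <- vapply(frags, .obCanonical, "")
            if (anyNA(can))
                stop("cannot parse SMILES fragment in input ", i, ": '",
                     s, "'", call. = FALSE)
            # heavy-atom count per fragment decides which one survives
            nat <- vapply(.parseGraphs(can),
                          function(g) length(g$elem), 1L)
            stripped <<- TRUE
            can[which.max(nat)]
        } else {
            can <- .obCanonical(s)
            if (is.na(can))
                stop("cannot parse SMILES in input ", i, ": '", s, "'",
                     call. = FALSE)
            can
        }
    }, "")
    if (stripped)
        warning("multi-fragment input: kept the largest covalent fragment")
    graphs <- .parseGraphs(canonical)
    nAtoms <- vapply(graphs, function(g) length(g$elem), 1L)
    nBonds <- vapply(graphs, function(g) nrow(g$bonds), 1L)
    if (is.null(ids)) ids <- canonical
    new("MoleculeSet", smiles = canonical, molId = as.character(ids),
        atomCount = nAtoms, ringFlag = nBonds >= nAtoms)
}

#' @rdname parseMolecules
#' @param smi a single SMILES string.
#' @export
parseMolecule <- function(smi, ids = NULL) {
    stopifnot(length(smi) == 1L)
    parseMolecules(smi, ids)
}

.asMoleculeSet <- function(x) {
    if (is(x, "MoleculeSet")) x
    else if (is.character(x)) parseMolecules(x)
    else stop("expected a MoleculeSet or a character vector of SMILES")
}

## ---- Morgan fingerprint -------------------------------------------------

# OpenBabel's ECFP4 (circular, radius 2) is a 4096-bit vector; fold by
# OR-ing the four 1024-bit chunks to obtain the conventional 1024-bit form.
.fold1024 <- function(m) {
    folded <- (m[, 1:1024, drop = FALSE] | m[, 1025:2048, drop = FALSE] |
               m[, 2049:3072, drop = FALSE] | m[, 3073:4096, drop = FALSE])
    storage.mode(folded) <- "integer"
    folded
}

# hex digit -> 4 bits (high to low), fixed decode table
.hexBits <- local({
    m <- matrix(0L, 16L, 4L)
    for (v in 0:15)
        m[v + 1L, ] <- as.integer(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0L)
    m
})

# Batch ECFP4 through the obabel command line (one subprocess for the
# whole batch; hex fingerprint text output). Input must already be
# canonical/parseable so that no molecule is silently dropped.
.computeMorgan <- function(canonical) {
    smiFile <- tempfile(fileext = ".smi")
    fptFile <- tempfile(fileext = ".fpt")
    on.exit(unlink(c(smiFile, fptFile)))
    writeLines(paste0(canonical, "\tm", seq_along(canonical)), smiFile)
    status <- suppressWarnings(
        system2("obabel", c(smiFile, "-ofpt", "-xfECFP4", "-xh"),
                stdout = fptFile, stderr = FALSE))
    if (status != 0L)
        stop("obabel fingerprint run failed (is OpenBabel on the PATH?)")
    lines <- readLines(fptFile)
    hdr <- grep("^>", lines)
    if (length(hdr) != length(canonical))
        stop("fingerprinting dropped molecules; invalid SMILES?")
    ends <- c(hdr[-1L] - 1L, length(lines))
    hexes <- vapply(seq_along(hdr), function(i)
        gsub("[^0-9a-f]", "",
             paste(lines[(hdr[i] + 1L):ends[i]], collapse = "")), "")
    if (any(nchar(hexes) != 1024L))
        stop("unexpected fingerprint block size from obabel")
    chars <- strsplit(paste(hexes, collapse = ""), "")[[1L]]
    vals <- match(chars, c(as.character(0:9), letters[1:6])) - 1L
    bits <- as.vector(t(.hexBits[vals + 1L, , drop = FALSE]))
    .fold1024(matrix(bits, nrow = length(canonical), ncol = 4096L,
                     byrow = TRUE))
}

#' 1024-bit Morgan fingerprint (radius 2)
#'
#' Circular substructure fingerprint of radius 2 (ECFP4-class), folded to
#' 1024 bits. Deterministic for a given canonical structure and invariant
#' to input atom ordering. Hashing runs through one batched OpenBabel
#' subprocess per call, and results are memoised per canonical SMILES for
#' the session, so repeated fingerprinting of the same molecules is free.
#'
#' @param x a \code{MoleculeSet} or character vector of SMILES.
#' @return Integer 0/1 matrix with one row per molecule and 1024 columns,
#'   row names set to the molecule ids.
#' @examples
#' fp <- morganFingerprint(parseMolecules("CCO"))
#' dim(fp)  # 1 x 1024
#' @export
morganFingerprint <- function(x) {
    mols <- .asMoleculeSet(x)
    can <- mols@smiles
    cache <- .pkgEnv$fpCache
    missing <- unique(can[!vapply(can, exists, TRUE, envir = cache,
                                  inherits = FALSE)])
    if (length(missing) > 0L) {
        fresh <- .computeMorgan(missing)
        for (i in seq_along(missing))
            assign(missing[i], fresh[i, ], envir = cache)
    }
    out <- matrix(0L, nrow = length(can), ncol = 1024L)
    for (i in seq_along(can))
        out[i, ] <- get(can[i], envir = cache, inherits = FALSE)
    rownames(out) <- mols@molId
    colnames(out) <- paste0("b", seq_len(1024L))
    out
}

## ---- Bemis-Murcko scaffold and cyclic skeleton --------------------------

# Scaffold atoms: the 2-core of the heavy-atom graph (iterative pruning of
# degree-1 atoms, which removes side chains and keeps rings plus the linker
# paths between them) plus any atom attached to the core by a bond of order
# >= 2 (exocyclic doubly-bonded atoms, e.g. ring carbonyl oxygens).
.scaffoldAtoms <- function(nAtoms, bonds) {
    keep <- rep(TRUE, nAtoms)
    repeat {
        deg <- integer(nAtoms)
        live <- keep[bonds[, 1L]] & keep[bonds[, 2L]]
        if (any(live)) {
            t1 <- tabulate(bonds[live, 1L], nAtoms)
            t2 <- tabulate(bonds[live, 2L], nAtoms)
            deg <- t1 + t2
        }
        leaf <- keep & deg <= 1L
        if (!any(leaf)) break
        keep[leaf] <- FALSE
    }
    if (!any(keep)) return(NULL)
    core <- keep
    exo <- (bonds[, 3L] >= 2L) &
        (core[bonds[, 1L]] != core[bonds[, 2L]])
    add <- unique(c(bonds[exo & !core[bonds[, 1L]], 1L],
                    bonds[exo & !core[bonds[, 2L]], 2L]))
    list(core = which(core), full = sort(c(which(core), add)))
}

# Minimal SMILES writer for a connected heavy-atom subgraph (kekulized bond
# orders, no charges or stereo). Output is fed straight back through
# OpenBabel canonicalization, so only syntactic validity matters here.
.writeSmilesGraph <- function(elem, bonds) {
    n <- length(elem)
    organic <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
    atomTok <- ifelse(elem %in% organic, elem, paste0("[", elem, "]"))
    bondTok <- c("", "=", "#", "$")
    adj <- vector("list", n)
    if (nrow(bonds) > 0L) {
        for (b in seq_len(nrow(bonds))) {
            i <- bonds[b, 1L]; j <- bonds[b, 2L]; o <- bonds[b, 3L]
            adj[[i]] <- rbind(adj[[i]], c(j, o))
            adj[[j]] <- rbind(adj[[j]], c(i, o))
        }
    }
    st <- new.env(parent = emptyenv())
    st$visited <- rep(FALSE, n)
    st$closure <- vector("list", n)   # per-atom ring-closure tokens
    st$treeKids <- vector("list", n)  # (child, order) in visit order
    st$nextDigit <- 1L
    st$seenEdge <- new.env(parent = emptyenv())
    edgeKey <- function(i, j) paste(min(i, j), max(i, j))
    dfs <- function(v, parent) {
        st$visited[v] <- TRUE
        nb <- adj[[v]]
        if (is.null(nb)) return(invisible())
        for (r in seq_len(nrow(nb))) {
            w <- nb[r, 1L]; o <- nb[r, 2L]
            if (w == parent && is.null(st$seenEdge[[edgeKey(v, w)]])) {
                st$seenEdge[[edgeKey(v, w)]] <- TRUE
                next
            }
            key <- edgeKey(v, w)
            if (!is.null(st$seenEdge[[key]])) next
            st$seenEdge[[key]] <- TRUE
            if (st$visited[w]) {  # back edge -> ring closure
                d <- st$nextDigit
                st$nextDigit <- d + 1L
                tok <- if (d < 10L) paste0(bondTok[o], d) else
                    paste0(bondTok[o], "%", d)
                st$closure[[v]] <- c(st$closure[[v]], tok)
                st$closure[[w]] <- c(st$closure[[w]], tok)
            } else {
                st$treeKids[[v]] <- rbind(st$treeKids[[v]], c(w, o))
                dfs(w, v)
            }
        }
        invisible()
    }
    dfs(1L, 0L)
    if (!all(st$visited))
        stop("internal: scaffold subgraph is not connected")
    build <- function(v, orderIn) {
        out <- if (orderIn > 0L) bondTok[orderIn] else ""
        out <- paste0(out, atomTok[v],
                      paste(st$closure[[v]], collapse = ""))
        kids <- st$treeKids[[v]]
        if (!is.null(kids)) {
            nk <- nrow(kids)
            for (r in seq_len(nk)) {
                sub <- build(kids[r, 1L], kids[r, 2L])
                out <- if (r < nk) paste0(out, "(", sub, ")")
                       else paste0(out, sub)
            }
        }
        out
    }
    build(1L, 0L)
}

# Scaffold and CSK SMILES (non-canonical) for one molecule graph; NULL
# when the molecule is acyclic. The Bemis-Murcko scaffold keeps exocyclic
# multiply-bonded atoms; the CSK is reduced to the ring-and-linker core so
# that flattening bond orders cannot create new prunable side chains
# (making the reduction idempotent).
.scaffoldAndCsk <- function(graph) {
    sel <- .scaffoldAtoms(length(graph$elem), graph$bonds)
    if (is.null(sel)) return(NULL)
    subgraph <- function(atoms) {
        remap <- integer(length(graph$elem))
        remap[atoms] <- seq_along(atoms)
        inSel <- logical(length(graph$elem)); inSel[atoms] <- TRUE
        b <- graph$bonds[inSel[graph$bonds[, 1L]] &
                         inSel[graph$bonds[, 2L]], , drop = FALSE]
        cbind(remap[b[, 1L]], remap[b[, 2L]], b[, 3L])
    }
    bFull <- subgraph(sel$full)
    scaf <- .writeSmilesGraph(graph$elem[sel$full], bFull)
    bCore <- subgraph(sel$core)
    bCore[, 3L] <- 1L
    csk <- .writeSmilesGraph(rep("C", length(sel$core)), bCore)
    list(scaffold = scaf, csk = csk)
}

#' Cyclic skeleton (CSK) of the Bemis-Murcko scaffold
#'
#' The Bemis-Murcko scaffold is the ring-and-linker framework of a molecule
#' (side chains pruned; atoms attached to the framework by double or triple
#' bonds are retained). The cyclic skeleton reduces it further by replacing
#' every heavy atom with carbon and setting every bond order to one, so
#' that molecules differing only in heteroatoms or bond orders within the
#' scaffold share a CSK. Canonical CSK SMILES equality defines chemotype
#' equality. Chirality and charges are discarded.
#'
#' @param x a \code{MoleculeSet} or character vector of SMILES.
#' @param onAcyclic what to do with ring-less molecules: \code{"error"}
#'   (default) or \code{"na"} to emit \code{NA} entries (callers exclude
#'   such compounds from scaffold analyses).
#' @return A \code{\linkS4class{CyclicSkeletonSet}}.
#' @examples
#' cskSmiles(cyclicSkeleton("c1ccncc1"))  # "C1CCCCC1"
#' @export
cyclicSkeleton <- function(x, onAcyclic = c("error", "na")) {
    onAcyclic <- match.arg(onAcyclic)
    mols <- .asMoleculeSet(x)
    graphs <- .parseGraphs(mols@smiles)
    raw <- lapply(graphs, .scaffoldAndCsk)
    bad <- vapply(raw, is.null, TRUE)
    if (any(bad) && onAcyclic == "error")
        stop("no scaffold: molecule without a ring ('",
             mols@smiles[which(bad)[1L]], "')")
    canonicalize <- function(s) {
        out <- vapply(s, .obCanonical, "", USE.NAMES = FALSE)
        if (anyNA(out))
            stop("internal: scaffold SMILES failed to canonicalize")
        out
    }
    csk <- rep(NA_character_, length(raw))
    scaf <- rep(NA_character_, length(raw))
    if (any(!bad)) {
        csk[!bad] <- canonicalize(vapply(raw[!bad], `[[`, "", "csk"))
        scaf[!bad] <- canonicalize(vapply(raw[!bad], `[[`, "", "scaffold"))
    }
    new("CyclicSkeletonSet", cskSmiles = csk, scaffoldSmiles = scaf)
}

## ---- accessors and show methods -----------------------------------------

#' @rdname MoleculeSet-class
#' @export
setMethod("smiles", "MoleculeSet", function(x, ...) x@smiles)

#' @rdname MoleculeSet-class
#' @export
setMethod("atomCount", "MoleculeSet", function(x) x@atomCount)

#' @rdname MoleculeSet-class
#' @export
setMethod("ringFlag", "MoleculeSet", function(x) x@ringFlag)

#' @rdname MoleculeSet-class
#' @export
setMethod("length", "MoleculeSet", function(x) length(x@smiles))

#' @rdname MoleculeSet-class
#' @param i index.
#' @param j,drop ignored.
#' @export
setMethod("[", "MoleculeSet", function(x, i, j, ..., drop = TRUE) {
    new("MoleculeSet", smiles = x@smiles[i], molId = x@molId[i],
        atomCount = x@atomCount[i], ringFlag = x@ringFlag[i])
})

setMethod("show", "MoleculeSet", function(object) {
    cat("MoleculeSet of", length(object), "molecules\n")
    n <- min(3L, length(object))
    for (i in seq_len(n))
        cat("  ", object@molId[i], ": ", object@smiles[i], "\n", sep = "")
    if (length(object) > n) cat("  ...\n")
})

#' @rdname CyclicSkeletonSet-class
#' @export
setMethod("cskSmiles", "CyclicSkeletonSet", function(x) x@cskSmiles)

#' @rdname CyclicSkeletonSet-class
#' @export
setMethod("length", "CyclicSkeletonSet", function(x) length(x@cskSmiles))

setMethod("show", "CyclicSkeletonSet", function(object) {
    cat("CyclicSkeletonSet of", length(object), "skeletons;",
        length(unique(object@cskSmiles[!is.na(object@cskSmiles)])),
        "distinct\n")
})
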