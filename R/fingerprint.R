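#' Load a structural-key dictionary
#'
#' The dictionary defines the 166 public structural keys as one SMARTS pattern
#' (or computed handler) per key with a minimal match multiplicity. It is a
#' versioned plain-text asset: tab-separated columns `key`, `smarts`,
#' `min_count`, `comment`; lines starting with `#` are comments. Patterns
#' beginning with `@` are computed handlers rather than SMARTS
#' (`@none`, `@aromatic_ring_count`, `@fragment_count`).
#'
#' @param version dictionary version; `"v1"` is the packaged public 166-key set.
#' @param path optional path to an external dictionary file; overrides
#'   `version` lookup but the version string is still recorded.
#' @return a data.frame of class `xr_key_dictionary` with attribute `version`.
#' @export
load_key_dictionary <- function(version = "v1", path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", paste0("maccs_keys_", version, ".tsv"),
                        package = "crossreact")
    if (!nzchar(path)) stop("no packaged key dictionary for version '", version, "'")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^\\s*#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop("malformed key dictionary: ", path)
  d <- data.frame(
    key = as.integer(vapply(parts, `[`, character(1), 1L)),
    smarts = vapply(parts, `[`, character(1), 2L),
    min_count = as.integer(vapply(parts, `[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(d$key) || anyNA(d$min_count)) stop("malformed key dictionary: ", path)
  if (!identical(sort(d$key), seq_len(nrow(d))) )
    stop("key indices must be unique and dense 1..", nrow(d))
  if (any(d$min_count < 1L)) stop("min_count must be >= 1")
  d <- d[order(d$key), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, version = version, class = c("xr_key_dictionary", "data.frame"))
}

default_key_dictionary <- function() {
  if (is.null(.cr_cache$dict_v1)) .cr_cache$dict_v1 <- load_key_dictionary("v1")
  .cr_cache$dict_v1
}

dictionary_version <- function(dict) attr(dict, "version")

#' Compute a structural-key fingerprint
#'
#' Bit *k* is set when pattern *k* of the dictionary attains at least
#' `min_count` unique substructure matches in the compound. The compound must
#' be standardized first: structural keys are stereo-blind, so fingerprinting
#' an unstandardized structure would silently depend on meaningless input
#' detail.
#'
#' @param x a standardized [compound()].
#' @param dict a key dictionary from [load_key_dictionary()]; default the
#'   packaged `v1` set.
#' @return object of class `xr_fingerprint`: fields `name`, `version`, `bits`
#'   (integer 0/1 vector, one per key).
#' @export
compute_fingerprint <- function(x, dict = NULL) {
  stopifnot(is_compound(x))
  if (!isTRUE(x$standardized))
    stop("compound '", x$name, "' must be standardized before fingerprinting")
  if (is.null(dict)) dict <- default_key_dictionary()
  mol <- ChemmineOB::forEachMol("SMILES", x$smiles, identity)
  bits <- integer(nrow(dict))
  for (i in seq_len(nrow(dict))) {
    p <- dict$smarts[i]
    n <- switch(p,
      "@none" = 0L,
      "@aromatic_ring_count" = aromatic_ring_count(x$smiles),
      "@fragment_count" = length(strsplit(x$smiles, ".", fixed = TRUE)[[1]]),
      {
        cnt <- tryCatch(
          ChemmineOB::smartsSearch_OB(mol, p, uniqueMatches = TRUE),
          error = function(e) stop("key ", dict$key[i],
                                   ": SMARTS failed to compile: ", p))
        as.integer(cnt)
      })
    bits[i] <- as.integer(n >= dict$min_count[i])
  }
  structure(list(name = x$name, version = dictionary_version(dict), bits = bits),
            class = "xr_fingerprint")
}

aromatic_ring_count <- function(smiles) {
  if (!grepl("[a-z]", gsub("\\[[^]]*\\]", "", smiles)) && !grepl(":", smiles))
    return(0L)  # no aromatic atoms written; OB canonical SMILES is aromatic-lowercase
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  r <- ChemmineR::rings(sdf[[1]], type = "all", arom = TRUE)
  sum(unlist(r$AROMATIC))
}

#' @export
print.xr_fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint %s> %s: %d/%d bits set\n", x$version, x$name,
              sum(x$bits), length(x$bits)))
  invisible(x)
}

#' Fingerprint a list of compounds into a bit matrix
#'
#' @param compounds list of standardized compounds.
#' @inheritParams compute_fingerprint
#' @return integer matrix, one row per compound (rownames = names), with
#'   attribute `version`.
#' @export
fingerprint_matrix <- function(compounds, dict = NULL) {
  if (is.null(dict)) dict <- default_key_dictionary()
  fps <- lapply(unname(compounds), compute_fingerprint, dict = dict)
  m <- do.call(rbind, lapply(fps, `[[`, "bits"))
  rownames(m) <- vapply(fps, `[[`, character(1), "name")
  structure(m, version = dictionary_version(dict))
}

#' Tanimoto similarity of two fingerprints
#'
#' `c / (|a| + |b| - c)` where `c` is the number of shared set bits. Two
#' all-zero fingerprints are degenerate: by convention their similarity is 1
#' (and 0 against any non-empty fingerprint); a message is emitted because the
#' value carries no structural information.
#'
#' @param a,b `xr_fingerprint` objects (same dictionary version) or plain 0/1
#'   vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (inherits(a, "xr_fingerprint") && inherits(b, "xr_fingerprint")) {
    if (!identical(a$version, b$version))
      stop("dictionary version mismatch: ", a$version, " vs ", b$version)
    a <- a$bits; b <- b$bits
  }
  stopifnot(length(a) == length(b))
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na == 0L && nb == 0L) {
    message("tanimoto: both fingerprints empty; returning 1 by convention")
    return(1)
  }
  c_ <- sum(a != 0 & b != 0)
  c_ / (na + nb - c_)
}

#' Similarity of candidate compounds to assay targets
#'
#' Computes the Tanimoto similarity of every candidate to every target; one
#' row per (candidate, target) pair, ordered by target then candidate input
#' order.
#'
#' @param targets,candidates lists of standardized compounds.
#' @inheritParams compute_fingerprint
#' @return data.frame with columns `query_name` (candidate), `reference_name`
#'   (target), `tanimoto`.
#' @export
similarity_panel <- function(targets, candidates, dict = NULL) {
  if (is.null(dict)) dict <- default_key_dictionary()
  empty <- data.frame(query_name = character(0), reference_name = character(0),
                      tanimoto = numeric(0), stringsAsFactors = FALSE)
  if (length(candidates) == 0L || length(targets) == 0L) return(empty)
  tm <- fingerprint_matrix(targets, dict)
  cm <- fingerprint_matrix(candidates, dict)
  out <- do.call(rbind, lapply(seq_len(nrow(tm)), function(i) {
    sims <- vapply(seq_len(nrow(cm)),
                   function(j) tanimoto(cm[j, ], tm[i, ]), numeric(1))
    data.frame(query_name = rownames(cm), reference_name = rownames(tm)[i],
               tanimoto = sims, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Hex encoding of fingerprints
#'
#' Bits are packed most-significant-first in key order, zero-padded to a
#' multiple of 4, for compact CSV export.
#'
#' @param fp an `xr_fingerprint`.
#' @return hex string.
#' @export
fp_hex <- function(fp) {
  stopifnot(inherits(fp, "xr_fingerprint"))
  bits <- fp$bits
  pad <- (4 - length(bits) %% 4) %% 4
  bits <- c(bits, integer(pad))
  nib <- matrix(bits, nrow = 4)
  paste(sprintf("%x", as.integer(8 * nib[1, ] + 4 * nib[2, ] + 2 * nib[3, ] + nib[4, ])),
        collapse = "")
}

#' @rdname fp_hex
#' @param hex hex string from [fp_hex()].
#' @param n_bits number of keys in the dictionary (166 for `v1`).
#' @param version dictionary version to stamp on the result.
#' @param name compound name to carry.
#' @export
fp_from_hex <- function(hex, n_bits = 166L, version = "v1", name = "") {
  nib <- strtoi(strsplit(hex, "")[[1]], base = 16L)
  bits <- as.vector(vapply(nib, function(v) as.integer(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0),
                           integer(4)))
  structure(list(name = name, version = version, bits = bits[seq_len(n_bits)]),
            class = "xr_fingerprint")
}
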