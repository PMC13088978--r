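# Compound representation: binary fingerprints plus numeric physicochemical
# descriptors, and the Tanimoto geometry used for diversity picking and
# chemotype clustering.
#
# Two modes are first-class:
#   * structure mode  - records carry SMILES; fingerprints and descriptors
#     are computed with Open Babel (via ChemmineOB);
#   * abstract mode   - fingerprints (and optionally descriptors) are
#     supplied directly, e.g. by the synthetic-library generator, so the
#     whole screening loop is exercisable with no chemistry toolkit.

#' Featurization specification
#'
#' @param n_bits fingerprint length in bits (default 1024).
#' @param descriptors character vector of descriptor names to compute in
#'   structure mode, or the number of descriptor slots expected in abstract
#'   mode. Defaults to the package's frozen descriptor set
#'   ([default_descriptors()]).
#' @return a list of class `feature_spec`.
#' @export
feature_spec <- function(n_bits = 1024, descriptors = default_descriptors()) {
  assert_that(n_bits >= 8, "n_bits must be at least 8")
  structure(list(n_bits = as.integer(n_bits), descriptors = descriptors),
            class = "feature_spec")
}

#' The package's frozen physicochemical descriptor set
#'
#' Named descriptors computed by Open Babel in structure mode: molecular
#' weight, exact mass, octanol-water logP, molar refractivity, topological
#' polar surface area, hydrogen-bond acceptor counts (two definitions),
#' hydrogen-bond donor count, and fluorine count. Any user-supplied list (or
#' abstract descriptor block) is accepted in its place; the set in force is
#' recorded in the run manifest.
#'
#' @return character vector of descriptor names.
#' @export
default_descriptors <- function() {
  c("MW", "exactmass", "logP", "MR", "TPSA", "HBA1", "HBA2", "HBD", "nF")
}

ob_available <- function() requireNamespace("ChemmineOB", quietly = TRUE)

require_ob <- function() {
  if (!ob_available()) {
    stop_iterscreen("iterscreen_missing_backend",
                    "structure (SMILES) mode requires the ChemmineOB package")
  }
}

# Canonical SMILES via Open Babel; "" (unparseable) -> invalid-compound.
ob_canonical_smiles <- function(smiles) {
  require_ob()
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN",
                                               paste0(smiles, " mol"))),
    error = function(e) ""
  )
  if (!nzchar(out)) {
    stop_iterscreen("iterscreen_invalid_compound",
                    sprintf("unparseable structure: '%s'", smiles))
  }
  strsplit(out, "[\t\n]")[[1]][1]
}

# 1024-bit Open Babel FP2 fingerprint, folded down to n_bits if requested.
# Computed from the canonical SMILES so equivalent input strings map to
# identical fingerprints.
ob_fingerprint <- function(canonical, n_bits) {
  require_ob()
  fp <- tryCatch(
    ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", canonical, identity), "FP2"),
    error = function(e) NULL
  )
  if (is.null(fp)) {
    stop_iterscreen("iterscreen_invalid_compound",
                    sprintf("fingerprint failed for '%s'", canonical))
  }
  bits <- as.integer(as.vector(fp) != 0)
  fold_bits(bits, n_bits)
}

# OR-fold a bit vector down to length n_bits (no-op if already that length).
fold_bits <- function(bits, n_bits) {
  if (length(bits) == n_bits) return(bits)
  assert_that(length(bits) %% n_bits == 0,
              "fingerprint length must be a multiple of n_bits to fold")
  m <- matrix(bits, nrow = n_bits)
  as.integer(rowSums(m) > 0)
}

ob_descriptors <- function(canonical, names) {
  require_ob()
  mol <- ChemmineOB::forEachMol("SMILES", canonical, identity)
  props <- ChemmineOB::prop_OB(mol)
  props$exactmass <- ChemmineOB::exactMass_OB(mol)
  vals <- vapply(names, function(nm) {
    v <- props[[nm]]
    if (is.null(v) || !is.numeric(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  names(vals) <- names
  vals
}

#' Turn one compound record into a feature vector
#'
#' A compound record is a list with `compound_id` and at least one of
#' `smiles` (structure mode) or `fingerprint` (abstract mode; optionally with
#' `descriptors`). The result concatenates the binary fingerprint block and
#' the numeric descriptor block; featurization is a pure function of the
#' canonical structure and the spec, so equivalent SMILES strings yield
#' bitwise-identical vectors. Unparseable structures signal an
#' `iterscreen_invalid_compound` condition so callers can exclude and log
#' them, mirroring valid-data filtering.
#'
#' @param record list with `compound_id`, and `smiles` and/or `fingerprint`
#'   (0/1 vector of length `spec$n_bits`), optionally `descriptors`.
#' @param spec a [feature_spec()].
#' @return an object of class `feature_vector` with elements `bits`,
#'   `descriptors`, and `combined` (their concatenation).
#' @export
featurize <- function(record, spec = feature_spec()) {
  has_fp <- !is.null(record$fingerprint)
  has_smiles <- !is.null(record$smiles) && !is.na(record$smiles) &&
    nzchar(record$smiles)
  assert_that(has_fp || has_smiles,
              "record needs a smiles string or a supplied fingerprint")
  if (has_fp) {
    bits <- as.integer(record$fingerprint)
    assert_that(length(bits) == spec$n_bits && all(bits %in% c(0L, 1L)),
                "supplied fingerprint must be 0/1 of length n_bits")
    desc <- record$descriptors %||% numeric(0)
    desc <- as.numeric(desc)
  } else {
    canonical <- ob_canonical_smiles(record$smiles)
    bits <- ob_fingerprint(canonical, spec$n_bits)
    desc <- ob_descriptors(canonical, spec$descriptors)
  }
  structure(
    list(compound_id = record$compound_id %||% "", bits = bits,
         descriptors = desc, combined = c(bits, unname(desc))),
    class = "feature_vector"
  )
}

#' Tanimoto distance between two binary fingerprints
#'
#' `1 - |a AND b| / |a OR b|`; by convention the distance between two
#' all-zero vectors is 0.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return distance in \[0, 1\].
#' @examples
#' tanimoto_distance(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 0.5
#' @export
tanimoto_distance <- function(a, b) {
  assert_that(length(a) == length(b), "fingerprints must have equal length")
  a <- as.logical(a)
  b <- as.logical(b)
  union <- sum(a | b)
  if (union == 0) return(0)
  1 - sum(a & b) / union
}

# Tanimoto distance from every row of 0/1 matrix X to 0/1 vector v.
tanimoto_dist_to_vec <- function(X, v) {
  inter <- as.vector(X %*% v)
  union <- rowSums(X) + sum(v) - inter
  d <- 1 - inter / union
  d[union == 0] <- 0
  d
}

# Full pairwise Tanimoto distance matrix for 0/1 matrix X (rows = compounds).
tanimoto_dist_matrix <- function(X) {
  inter <- X %*% t(X)
  rs <- rowSums(X)
  union <- outer(rs, rs, "+") - inter
  d <- 1 - inter / union
  d[union == 0] <- 0
  dimnames(d) <- list(rownames(X), rownames(X))
  d
}

#' Assemble a screening library
#'
#' The in-memory container for a compound collection: a 0/1 fingerprint
#' matrix (rows named by compound id) and an optional aligned descriptor
#' matrix.
#'
#' @param fingerprints integer/numeric 0/1 matrix, one row per compound, with
#'   unique rownames giving compound ids.
#' @param descriptors optional numeric matrix with the same rownames.
#' @return an object of class `screen_library`.
#' @export
screen_library <- function(fingerprints, descriptors = NULL) {
  fingerprints <- as.matrix(fingerprints)
  assert_that(!is.null(rownames(fingerprints)) &&
                !anyDuplicated(rownames(fingerprints)),
              "fingerprint rows must carry unique compound ids")
  assert_that(all(fingerprints %in% c(0, 1)),
              "fingerprints must be binary")
  if (!is.null(descriptors)) {
    descriptors <- as.matrix(descriptors)
    assert_that(identical(rownames(descriptors), rownames(fingerprints)),
                "descriptor rows must align with fingerprint rows")
  }
  structure(list(ids = rownames(fingerprints),
                 fingerprints = fingerprints,
                 descriptors = descriptors),
            class = "screen_library")
}

#' @export
print.screen_library <- function(x, ...) {
  cat(sprintf("<screen_library> %d compounds, %d fingerprint bits%s\n",
              length(x$ids), ncol(x$fingerprints),
              if (is.null(x$descriptors)) ""
              else sprintf(", %d descriptors", ncol(x$descriptors))))
  invisible(x)
}

# Combined (fingerprint + descriptor) feature matrix with non-finite
# descriptor entries imputed to the per-column median of `train_ids` rows
# (tested compounds only, so no information leaks from untested rows).
combined_features <- function(library, train_ids = NULL) {
  X <- library$fingerprints
  colnames(X) <- paste0("b", seq_len(ncol(X)))
  if (!is.null(library$descriptors)) {
    D <- library$descriptors
    if (any(!is.finite(D))) {
      ref <- if (is.null(train_ids)) D else D[train_ids, , drop = FALSE]
      med <- apply(ref, 2, function(col) {
        m <- stats::median(col[is.finite(col)])
        if (is.finite(m)) m else 0
      })
      for (j in seq_len(ncol(D))) {
        bad <- !is.finite(D[, j])
        if (any(bad)) D[bad, j] <- med[j]
      }
    }
    colnames(D) <- paste0("d", seq_len(ncol(D)))
    X <- cbind(X, D)
  }
  X
}
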