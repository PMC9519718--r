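#' Filter a marker matrix on allele frequency and missingness
#'
#' Removes monomorphic markers and markers failing the minor allele frequency
#' or missingness thresholds, computed on observed entries of the -1/0/1
#' coding. The defaults mirror the permissive filters commonly used before
#' building a genomic relationship matrix (minor allele frequency > 0.002%
#' and missing frequency < 0.998%).
#'
#' @param M Genotype-by-marker matrix coded -1/0/1 with `NA` for missing;
#'   rows are genotypes, columns named markers.
#' @param maf_min Minimum minor allele frequency (exclusive), in `[0, 1]`.
#' @param missing_max Maximum missing fraction (exclusive), in `[0, 1]`.
#' @return A `marker_matrix` object: list with `M` (retained columns, still
#'   possibly containing `NA`), `retained` (marker names), `m` (retained
#'   count) and `dropped` (named reasons).
#' @export
filter_markers <- function(M, maf_min = 0.002 / 100, missing_max = 0.998 / 100) {
  assert_that(is.matrix(M) && is.numeric(M), "M must be a numeric matrix",
              class = "metfa_input_error")
  assert_that(maf_min >= 0 && maf_min <= 1 && missing_max >= 0 && missing_max <= 1,
              "thresholds must lie in [0, 1]", class = "metfa_input_error")
  if (is.null(colnames(M))) colnames(M) <- paste0("m", seq_len(ncol(M)))

  miss_frac <- colMeans(is.na(M))
  # allele frequency of the "1" allele from -1/0/1 dosages on observed entries
  af <- vapply(seq_len(ncol(M)), function(i) {
    x <- M[!is.na(M[, i]), i]
    if (length(x) == 0L) return(NA_real_)
    mean((x + 1) / 2)
  }, numeric(1L))
  maf <- pmin(af, 1 - af)
  mono <- vapply(seq_len(ncol(M)), function(i) {
    x <- unique(M[!is.na(M[, i]), i])
    length(x) <= 1L
  }, logical(1L))

  reason <- rep(NA_character_, ncol(M))
  reason[miss_frac >= missing_max | is.na(maf)] <- "missingness"
  reason[is.na(reason) & mono] <- "monomorphic"
  reason[is.na(reason) & maf <= maf_min] <- "maf"
  keep <- is.na(reason)
  assert_that(any(keep), "no markers survive filtering", class = "metfa_filter_error")

  dropped <- reason[!keep]
  names(dropped) <- colnames(M)[!keep]
  structure(list(M = M[, keep, drop = FALSE],
                 retained = colnames(M)[keep],
                 m = sum(keep),
                 dropped = dropped),
            class = "marker_matrix")
}

#' Impute missing marker scores by k-nearest neighbours
#'
#' Each missing entry is replaced by the unweighted mean of the entry in the
#' `k` nearest genotypes, with distance the root mean squared difference over
#' mutually observed markers. Only genotypes with that marker observed are
#' candidate neighbours; ties are broken by genotype (row) order. Observed
#' entries are never modified and imputed values are left continuous.
#'
#' @param M Genotype-by-marker matrix (or a `marker_matrix`) with `NA` missing.
#' @param k Number of neighbours (default 10).
#' @return A complete numeric matrix of the same shape (a plain matrix).
#' @export
impute_markers_knn <- function(M, k = 10L) {
  if (inherits(M, "marker_matrix")) M <- M$M
  assert_that(is.matrix(M) && is.numeric(M), "M must be a numeric matrix",
              class = "metfa_input_error")
  assert_that(k >= 1L, "k must be at least 1", class = "metfa_input_error")
  if (!anyNA(M)) return(M)

  all_missing <- rowSums(!is.na(M)) == 0L
  if (any(all_missing)) {
    ids <- rownames(M) %||% as.character(which(all_missing))
    stop_metfa(paste0("genotype(s) with no observed markers: ",
                      paste(ids[all_missing], collapse = ", ")),
               class = "metfa_impute_error")
  }

  v <- nrow(M)
  obs <- !is.na(M)
  M0 <- M; M0[!obs] <- 0
  # pairwise mean squared difference over mutually observed markers:
  # msd_ab = (||x||^2 + ||y||^2 - 2 x.y over shared) / n_shared
  shared <- tcrossprod(obs * 1)
  cross <- tcrossprod(M0 * obs)
  sq <- tcrossprod(M0^2, obs * 1)              # sum over shared of x^2
  d2 <- sq + t(sq) - 2 * cross
  d2 <- d2 / pmax(shared, 1L)
  d2[shared == 0L] <- Inf
  diag(d2) <- Inf

  out <- M
  for (g in which(rowSums(!obs) > 0L)) {
    miss_cols <- which(!obs[g, ])
    ord <- order(d2[g, ], seq_len(v))          # stable: ties by genotype index
    for (j in miss_cols) {
      donors <- ord[obs[ord, j] & is.finite(d2[g, ord])]
      if (length(donors) == 0L) {
        # no informative donor shares markers with g for this column
        donors <- which(obs[, j])
      }
      use <- donors[seq_len(min(k, length(donors)))]
      out[g, j] <- mean(M[use, j])
    }
  }
  out
}

#' Genomic relationship matrix from centred marker scores
#'
#' Computes the VanRaden-style relationship matrix `G_g = M M' / m` from
#' column-centred marker scores, with `m` the retained marker count. Column
#' centring implies zero row and column sums, so `G_g` is singular; a ridge
#' can be added to the diagonal for use inside mixed-model solves.
#'
#' @param M Complete genotype-by-marker matrix (or a `marker_matrix` whose `M`
#'   is complete). Columns are centred here; pre-centred input is unchanged.
#' @param ridge Non-negative diagonal ridge (default 0).
#' @return A `genomic_relationship` object: list with `G` (v x v, including
#'   any ridge), `ridge`, and `m` (marker count used in the divisor).
#' @export
compute_grm <- function(M, ridge = 0) {
  if (inherits(M, "marker_matrix")) M <- M$M
  assert_that(is.matrix(M) && is.numeric(M), "M must be a numeric matrix",
              class = "metfa_input_error")
  assert_that(ncol(M) >= 1L, "need at least one marker", class = "metfa_input_error")
  assert_that(ridge >= 0, "ridge must be non-negative", class = "metfa_input_error")
  Mc <- centre_columns(M)
  G <- tcrossprod(Mc) / ncol(Mc)
  if (ridge > 0) G <- G + diag(ridge, nrow(G))
  dimnames(G) <- list(rownames(M), rownames(M))
  structure(list(G = G, ridge = ridge, m = ncol(Mc)), class = "genomic_relationship")
}

#' @export
print.genomic_relationship <- function(x, ...) {
  cat("<genomic_relationship> ", nrow(x$G), " genotypes, m = ", x$m,
      " markers, ridge = ", format(x$ridge), "\n", sep = "")
  invisible(x)
}

#' Read and write marker and relationship matrices
#'
#' Markers travel as delimited text with genotypes in rows (first column
#' `genotype`) and one column per marker; empty fields are missing. The GRM
#' travels as a square delimited matrix with a genotype header row and column.
#'
#' @param path File path.
#' @return `read_markers()` returns a numeric matrix with genotype rownames;
#'   `read_grm()` a `genomic_relationship`.
#' @export
read_markers <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         colClasses = c(genotype = "character"))
  M <- as.matrix(tab[setdiff(names(tab), "genotype")])
  storage.mode(M) <- "double"
  rownames(M) <- tab$genotype
  M
}

#' @rdname read_markers
#' @param M Matrix with genotype rownames.
#' @export
write_markers <- function(M, path) {
  out <- data.frame(genotype = rownames(M), M, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname read_markers
#' @export
read_grm <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         colClasses = c(genotype = "character"))
  G <- as.matrix(tab[setdiff(names(tab), "genotype")])
  storage.mode(G) <- "double"
  rownames(G) <- tab$genotype
  structure(list(G = G, ridge = 0, m = NA_integer_), class = "genomic_relationship")
}

#' @rdname read_markers
#' @param grm A `genomic_relationship` or square matrix with dimnames.
#' @export
write_grm <- function(grm, path) {
  G <- if (inherits(grm, "genomic_relationship")) grm$G else grm
  out <- data.frame(genotype = rownames(G), G, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
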