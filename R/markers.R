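#' Marker score matrix
#'
#' Container for a panel of genotypes scored at biallelic markers. Scores use
#' the -1/0/+1 coding: -1 is the minor-allele homozygote, 0 the heterozygote
#' and +1 the major-allele homozygote.
#'
#' @param scores Integer matrix, genotypes in rows, markers in columns, all
#'   entries in \{-1, 0, 1\}.
#' @param genotype_ids Character vector of unique genotype labels, one per row.
#' @param marker_ids Character vector of unique marker labels, one per column.
#' @return An object of class `marker_matrix` with elements `scores`,
#'   `genotype_ids` and `marker_ids`.
#' @export
marker_matrix <- function(scores, genotype_ids = rownames(scores),
                          marker_ids = colnames(scores)) {
  scores <- as.matrix(scores)
  if (is.null(genotype_ids)) genotype_ids <- paste0("g", seq_len(nrow(scores)))
  if (is.null(marker_ids)) marker_ids <- paste0("m", seq_len(ncol(scores)))
  genotype_ids <- as.character(genotype_ids)
  marker_ids <- as.character(marker_ids)
  if (nrow(scores) < 2L) stop("need at least 2 genotypes", call. = FALSE)
  if (ncol(scores) < 1L) stop("need at least 1 marker", call. = FALSE)
  if (anyNA(scores)) stop("marker scores contain missing values", call. = FALSE)
  if (!all(scores %in% c(-1L, 0L, 1L))) {
    stop("marker scores must all be -1, 0 or 1", call. = FALSE)
  }
  if (length(genotype_ids) != nrow(scores) || anyDuplicated(genotype_ids)) {
    stop("genotype_ids must be unique and match the number of rows", call. = FALSE)
  }
  if (length(marker_ids) != ncol(scores) || anyDuplicated(marker_ids)) {
    stop("marker_ids must be unique and match the number of columns", call. = FALSE)
  }
  storage.mode(scores) <- "integer"
  dimnames(scores) <- list(genotype_ids, marker_ids)
  structure(list(scores = scores, genotype_ids = genotype_ids,
                 marker_ids = marker_ids),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("marker_matrix:", nrow(x$scores), "genotypes x", ncol(x$scores),
      "markers (-1/0/+1 coding)\n")
  invisible(x)
}

# Orient 0/1/2 allele dosages so that +1 is the major-allele homozygote.
# `dos` counts copies of one (arbitrary) allele; if that allele is the minor
# one the column is flipped. A 50/50 frequency keeps the file orientation.
orient_dosage <- function(dos) {
  n2 <- 2L * nrow(dos)
  f <- colSums(dos) / n2  # frequency of the counted allele
  flip <- f < 0.5
  out <- dos - 1L
  out[, flip] <- 1L - dos[, flip, drop = FALSE]
  out
}

#' Read a marker matrix from a delimited file or VCF
#'
#' Delimited files carry a header row of marker ids and genotype ids in the
#' first column; the separator (tab or comma) is autodetected. VCF input
#' (requires the vcfR package) uses the diploid GT field of biallelic sites;
#' multi-allelic sites are skipped with a warning. Input coded 0/1/2 is
#' recoded to -1/0/+1 by orienting each marker so that +1 is the homozygote
#' of the more frequent allele (frequency ties keep the file orientation).
#'
#' @param path Path to the input file.
#' @param format `"delimited"` or `"vcf"`.
#' @param coding For delimited input: `"auto"` (detect from the values),
#'   `"minus1_0_1"` (taken as already oriented) or `"0_1_2"`.
#' @param missing_policy `"error"` (default) or `"mean_impute"`, which
#'   replaces missing cells by the column mean rounded to the nearest score.
#' @return A [marker_matrix].
#' @export
load_markers <- function(path, format = c("delimited", "vcf"),
                         coding = c("auto", "minus1_0_1", "0_1_2"),
                         missing_policy = c("error", "mean_impute")) {
  format <- match.arg(format)
  coding <- match.arg(coding)
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  if (format == "vcf") {
    raw <- read_vcf_dosage(path)  # 0/1/2 dosages with NA for missing GT
    coding <- "0_1_2"
  } else {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                             check.names = FALSE, stringsAsFactors = FALSE)
    raw <- as.matrix(tab)
    if (!is.numeric(raw)) stop("non-numeric marker scores in ", path, call. = FALSE)
  }
  if (anyDuplicated(rownames(raw))) stop("duplicate genotype ids", call. = FALSE)

  if (anyNA(raw)) {
    if (missing_policy == "error") {
      stop("missing marker scores (use missing_policy = 'mean_impute')",
           call. = FALSE)
    }
    for (j in which(colSums(is.na(raw)) > 0L)) {
      mu <- mean(raw[, j], na.rm = TRUE)
      if (is.nan(mu)) mu <- if (format == "vcf" || coding == "0_1_2") 1 else 0
      raw[is.na(raw[, j]), j] <- round(mu)
    }
  }

  if (coding == "auto") {
    vals <- unique(as.vector(raw))
    coding <- if (any(vals < 0)) "minus1_0_1" else "0_1_2"
  }
  if (coding == "0_1_2") {
    if (!all(raw %in% 0:2)) stop("unknown coding symbols (expected 0/1/2)", call. = FALSE)
    scores <- orient_dosage(raw)
  } else {
    if (!all(raw %in% c(-1, 0, 1))) {
      stop("unknown coding symbols (expected -1/0/1)", call. = FALSE)
    }
    scores <- raw
  }
  marker_matrix(scores, rownames(raw), colnames(raw))
}

# Extract 0/1/2 ALT dosages from the GT field of a VCF; biallelic diploid
# sites only, genotypes in columns of the returned matrix's rows.
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF input requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) skipped")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0L) stop("no usable biallelic sites in VCF", call. = FALSE)
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2L || any(al == ".")) return(NA_integer_)
    sum(al == "1")
  })
  ids <- rownames(dos)
  if (is.null(ids)) ids <- paste0("site", seq_len(nrow(dos)))
  out <- t(dos)
  colnames(out) <- ids
  out
}

#' Filter markers by minor allele frequency
#'
#' MAF is computed from the -1/0/+1 scores as
#' (2 x count(-1) + count(0)) / (2 x n); markers whose MAF falls below the
#' threshold are dropped, preserving the order of survivors.
#'
#' @param m A [marker_matrix].
#' @param threshold MAF threshold in \[0, 0.5\]; markers with MAF >= threshold
#'   are retained.
#' @return A [marker_matrix] with the surviving markers.
#' @export
filter_maf <- function(m, threshold = 0.05) {
  stopifnot(inherits(m, "marker_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 0.5) {
    stop("threshold must be in [0, 0.5]", call. = FALSE)
  }
  maf <- marker_maf(m)
  keep <- maf >= threshold
  if (!any(keep)) stop("no markers pass the MAF threshold", call. = FALSE)
  marker_matrix(m$scores[, keep, drop = FALSE], m$genotype_ids,
                m$marker_ids[keep])
}

#' Per-marker minor allele frequency
#'
#' @param m A [marker_matrix].
#' @return Numeric vector of MAF values, one per marker.
#' @export
marker_maf <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  s <- m$scores
  (2 * colSums(s == -1L) + colSums(s == 0L)) / (2 * nrow(s))
}

#' Column-standardize a marker matrix
#'
#' Each marker column is centred by its sample mean and scaled by its sample
#' standard deviation (denominator n - 1). Zero-variance (monomorphic)
#' columns carry no relationship information and are dropped with a warning.
#'
#' @param m A [marker_matrix].
#' @return An object of class `standardized_markers` with elements `w`
#'   (numeric matrix), `kept_marker_ids` and `dropped_marker_ids`.
#' @export
standardize_markers <- function(m) {
  stopifnot(inherits(m, "marker_matrix"))
  x <- m$scores
  sds <- apply(x, 2L, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all markers are monomorphic; nothing to standardize", call. = FALSE)
  if (!all(keep)) {
    warning(sum(!keep), " monomorphic marker(s) dropped during standardization")
  }
  x <- x[, keep, drop = FALSE]
  w <- scale(x, center = TRUE, scale = sds[keep])
  attr(w, "scaled:center") <- NULL
  attr(w, "scaled:scale") <- NULL
  structure(list(w = w,
                 kept_marker_ids = m$marker_ids[keep],
                 dropped_marker_ids = m$marker_ids[!keep],
                 genotype_ids = m$genotype_ids),
            class = "standardized_markers")
}

#' Genomic relationship matrix
#'
#' K = W W' / p from column-standardized marker scores W with p retained
#' markers. By construction every row of K sums to zero and the trace equals
#' n - 1.
#'
#' @param w A `standardized_markers` object from [standardize_markers()], or
#'   a [marker_matrix] (standardized internally).
#' @return An object of class `genomic_relationship` with elements `K`
#'   (symmetric n x n matrix) and `genotype_ids`.
#' @export
compute_grm <- function(w) {
  if (inherits(w, "marker_matrix")) w <- standardize_markers(w)
  stopifnot(inherits(w, "standardized_markers"))
  p <- ncol(w$w)
  if (p < 1L) stop("no retained markers", call. = FALSE)
  K <- tcrossprod(w$w) / p
  K <- (K + t(K)) / 2
  dimnames(K) <- list(w$genotype_ids, w$genotype_ids)
  structure(list(K = K, genotype_ids = w$genotype_ids),
            class = "genomic_relationship")
}

#' @export
print.genomic_relationship <- function(x, ...) {
  cat("genomic_relationship:", nrow(x$K), "genotypes, trace =",
      format(sum(diag(x$K)), digits = 6), "\n")
  invisible(x)
}

#' Write / read a genomic relationship matrix as TSV
#'
#' The full symmetric matrix is stored with genotype ids as both the header
#' and the first column.
#'
#' @param g A `genomic_relationship`.
#' @param path Output (or input) file path.
#' @return `write_grm` returns `path` invisibly; `read_grm` returns a
#'   `genomic_relationship`.
#' @export
write_grm <- function(g, path) {
  stopifnot(inherits(g, "genomic_relationship"))
  tab <- data.frame(id = g$genotype_ids, g$K, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                           check.names = FALSE)
  K <- as.matrix(tab)
  if (nrow(K) != ncol(K) || !isTRUE(all.equal(rownames(K), colnames(K)))) {
    stop("malformed GRM file: expected a square matrix with matching ids", call. = FALSE)
  }
  K <- (K + t(K)) / 2
  structure(list(K = K, genotype_ids = rownames(K)),
            class = "genomic_relationship")
}

#' Simulate a structured inbred marker panel
#'
#' Generates a synthetic diversity panel resembling elite inbred lines. Each
#' marker draws an ancestral minor-allele frequency uniformly on `maf_range`;
#' with more than one subpopulation, subpopulation frequencies are drawn from
#' a Balding-Nichols Beta distribution around the ancestral frequency with
#' differentiation `fst`. Genotypes are sampled with strong inbreeding
#' (heterozygosity at 5 percent of its Hardy-Weinberg expectation), then each
#' marker is oriented so +1 is the major-allele homozygote.
#'
#' @param ncp Number of genotypes (>= 2).
#' @param p Number of markers (>= 1).
#' @param maf_range Ancestral minor-allele frequency range, a sub-interval of
#'   (0, 0.5\].
#' @param n_subpops Number of subpopulations (genotypes split evenly).
#' @param fst Differentiation between subpopulations in \[0, 1).
#' @param seed Integer seed; the draw is fully reproducible given the seed.
#' @return A [marker_matrix]; the subpopulation assignment is attached as
#'   attribute `"subpop"`.
#' @export
simulate_marker_matrix <- function(ncp, p, maf_range = c(0.05, 0.5),
                                   n_subpops = 1L, fst = 0, seed) {
  if (!is_count(ncp, 2L) || !is_count(p, 1L)) {
    stop("ncp must be >= 2 and p >= 1", call. = FALSE)
  }
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be within (0, 0.5]", call. = FALSE)
  }
  if (!is_count(n_subpops, 1L)) stop("n_subpops must be >= 1", call. = FALSE)
  if (fst < 0 || fst >= 1) stop("fst must be in [0, 1)", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)

  inbreeding <- 0.95  # residual heterozygosity = 5% of 2f(1-f)
  subpop <- rep(seq_len(n_subpops), length.out = ncp)
  subpop <- sort(subpop)

  dos <- with_seed(seed, {
    q <- stats::runif(p, maf_range[1], maf_range[2])  # ancestral minor freq
    freq <- matrix(q, n_subpops, p, byrow = TRUE)
    if (n_subpops > 1L && fst > 0) {
      a <- (1 - fst) / fst
      freq <- matrix(stats::rbeta(n_subpops * p,
                                  shape1 = rep(q, each = n_subpops) * a,
                                  shape2 = rep(1 - q, each = n_subpops) * a),
                     n_subpops, p)
      freq <- pmin(pmax(freq, 1e-6), 1 - 1e-6)
    }
    f <- freq[subpop, , drop = FALSE]  # per-individual minor-allele freq
    p_minor_hom <- f^2 + inbreeding * f * (1 - f)
    p_het <- 2 * f * (1 - f) * (1 - inbreeding)
    u <- matrix(stats::runif(ncp * p), ncp, p)
    # dosage of the ancestral-minor allele: 2, 1 or 0 copies
    ifelse(u < p_minor_hom, 0L, ifelse(u < p_minor_hom + p_het, 1L, 2L))
  })
  scores <- orient_dosage(dos)
  out <- marker_matrix(scores,
                       genotype_ids = sprintf("g%03d", seq_len(ncp)),
                       marker_ids = sprintf("m%04d", seq_len(p)))
  attr(out, "subpop") <- subpop
  out
}
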