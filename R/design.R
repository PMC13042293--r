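#' Per-environment training design
#'
#' An ordered list of candidate-index subsets S1..ST, one per environment.
#' Indices refer to rows of the candidate genomic relationship matrix.
#' Within an environment indices are duplicate-free; the same genotype may
#' appear in several environments.
#'
#' @param subsets List of integer vectors (1-based candidate indices).
#' @param ncp Number of candidates the indices refer to (for validation);
#'   optional.
#' @return An object of class `training_design` with elements `subsets` and
#'   `sizes`.
#' @export
training_design <- function(subsets, ncp = NULL) {
  if (!is.list(subsets) || length(subsets) < 1L) {
    stop("subsets must be a non-empty list of index vectors", call. = FALSE)
  }
  subsets <- lapply(subsets, function(s) as.integer(s))
  for (j in seq_along(subsets)) {
    s <- subsets[[j]]
    if (length(s) < 1L) stop("environment ", j, " has an empty subset", call. = FALSE)
    if (anyDuplicated(s)) stop("duplicate indices within environment ", j, call. = FALSE)
    if (any(s < 1L)) stop("indices must be >= 1", call. = FALSE)
    if (!is.null(ncp) && any(s > ncp)) {
      stop("index out of range in environment ", j, call. = FALSE)
    }
  }
  structure(list(subsets = subsets, sizes = lengths(subsets)),
            class = "training_design")
}

#' @export
print.training_design <- function(x, ...) {
  cat("training_design:", length(x$subsets), "environment(s), sizes",
      paste(x$sizes, collapse = "+"), "=", sum(x$sizes), "\n")
  invisible(x)
}

#' Draw a random training design
#'
#' The baseline construction method: each environment's subset is drawn
#' uniformly without replacement, independently across environments (overlap
#' across environments is allowed).
#'
#' @param ncp Number of candidates.
#' @param sizes Integer vector n1..nT of per-environment subset sizes.
#' @param seed Integer seed.
#' @return A [training_design].
#' @export
random_design <- function(ncp, sizes, seed) {
  if (any(sizes < 1L) || any(sizes > ncp)) {
    stop("each size must be in [1, ncp]", call. = FALSE)
  }
  subsets <- with_seed(seed, lapply(sizes, function(n) sort(sample.int(ncp, n))))
  training_design(subsets, ncp = ncp)
}

#' Read / write a training design as CSV
#'
#' The file has columns `genotype_id` and `environment`, one record per
#' genotype-environment pair. Environments are ordered by first appearance
#' when reading.
#'
#' @param design A [training_design].
#' @param genotype_ids Candidate labels that design indices refer to.
#' @param path File path.
#' @param environment_labels Optional environment names (defaults to E1..ET).
#' @return `write_design` returns `path` invisibly; `read_design` returns a
#'   [training_design] (with the environment labels as an attribute).
#' @export
write_design <- function(design, genotype_ids, path,
                         environment_labels = NULL) {
  stopifnot(inherits(design, "training_design"))
  tt <- length(design$subsets)
  labs <- environment_labels %||% paste0("E", seq_len(tt))
  tab <- do.call(rbind, lapply(seq_len(tt), function(j) {
    data.frame(genotype_id = genotype_ids[design$subsets[[j]]],
               environment = labs[j])
  }))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, genotype_ids) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("genotype_id", "environment") %in% names(tab))) {
    stop("design file needs columns genotype_id and environment", call. = FALSE)
  }
  idx <- match(tab$genotype_id, genotype_ids)
  if (anyNA(idx)) {
    stop("unknown genotype id(s): ",
         paste(utils::head(unique(tab$genotype_id[is.na(idx)]), 5L), collapse = ", "),
         call. = FALSE)
  }
  envs <- unique(tab$environment)
  subsets <- lapply(envs, function(e) idx[tab$environment == e])
  out <- training_design(subsets, ncp = length(genotype_ids))
  attr(out, "environment_labels") <- envs
  out
}
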