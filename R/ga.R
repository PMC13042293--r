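#' Genetic-algorithm settings for training-set search
#'
#' An elitist generational GA over per-environment subsets. The default
#' iteration floor of 12,000 favours near-global optima on real panels;
#' small problems converge long before it and can use a smaller floor.
#'
#' @param population_size Number of designs per generation (>= 2).
#' @param min_iterations Iterations to run before any stopping rule applies.
#' @param patience Consecutive non-improving iterations (after the floor)
#'   that trigger stopping.
#' @param elite_count Top designs copied unchanged into the next generation.
#' @param tournament_size Tournament size for parent selection.
#' @param mutation_rate Per-environment probability of swapping one selected
#'   index for an unselected one.
#' @param seed Integer seed (required); the search is deterministic given the
#'   seed, the config and the inputs.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(population_size = 50L, min_iterations = 12000L,
                      patience = 500L, elite_count = 1L,
                      tournament_size = 3L, mutation_rate = 0.1, seed) {
  if (!is_count(population_size, 2L)) stop("population_size must be >= 2", call. = FALSE)
  if (!is_count(min_iterations, 1L)) stop("min_iterations must be >= 1", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  structure(list(population_size = as.integer(population_size),
                 min_iterations = as.integer(min_iterations),
                 patience = as.integer(patience),
                 elite_count = as.integer(elite_count),
                 tournament_size = as.integer(tournament_size),
                 mutation_rate = mutation_rate,
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Optimize a training design under a CD criterion
#'
#' Searches the space of per-environment candidate subsets for a design
#' maximizing [cdmean_v2()] or [cdmean_met()]. Parents are chosen by
#' tournament; crossover samples each child subset from the union of the two
#' parents' subsets for that environment; mutation swaps a selected index
#' with an unselected one; elitism keeps the incumbent best, so the
#' best-score trace is non-decreasing. Stops at the iteration floor plus the
#' first `patience`-length non-improving streak.
#'
#' @param K A `genomic_relationship` (or symmetric matrix).
#' @param sizes Integer vector n1..nT of per-environment training sizes.
#' @param criterion A [criterion_spec].
#' @param cfg A [ga_config].
#' @return An object of class `optimization_result` with `best_design`,
#'   `best_score`, `trace` (best score per iteration), `iterations_run` and
#'   `seed`.
#' @export
optimize_design <- function(K, sizes, criterion = criterion_spec("cdmean_v2"),
                            cfg) {
  Km <- if (inherits(K, "genomic_relationship")) K$K else as.matrix(K)
  stopifnot(inherits(criterion, "criterion_spec"), inherits(cfg, "ga_config"))
  ncp <- nrow(Km)
  sizes <- as.integer(sizes)
  if (any(sizes < 1L) || any(sizes > ncp)) {
    stop("each training size must be in [1, ncp]", call. = FALSE)
  }
  tt <- length(sizes)
  vc <- criterion_vc_for(criterion, tt)
  fitness <- function(subsets) {
    s <- cd_score(Km, subsets, vc, criterion$name, warn = FALSE)
    if (!is.finite(s)) stop("non-finite criterion score", call. = FALSE)
    s
  }

  res <- with_seed(cfg$seed, {
    npop <- cfg$population_size
    pop <- replicate(npop, lapply(sizes, function(n) sample.int(ncp, n)),
                     simplify = FALSE)
    fit <- vapply(pop, fitness, numeric(1))
    best_i <- which.max(fit)
    best <- pop[[best_i]]
    best_fit <- fit[best_i]

    trace <- numeric(0)
    streak <- 0L
    iter <- 0L
    repeat {
      iter <- iter + 1L
      elite_idx <- order(fit, decreasing = TRUE)[seq_len(cfg$elite_count)]
      newpop <- pop[elite_idx]
      newfit <- fit[elite_idx]
      while (length(newpop) < npop) {
        pick <- function() {
          cand <- sample.int(npop, min(cfg$tournament_size, npop))
          pop[[cand[which.max(fit[cand])]]]
        }
        p1 <- pick(); p2 <- pick()
        child <- lapply(seq_len(tt), function(j) {
          pool <- unique(c(p1[[j]], p2[[j]]))
          if (length(pool) == sizes[j]) pool else sample(pool, sizes[j])
        })
        for (j in seq_len(tt)) {
          if (stats::runif(1) < cfg$mutation_rate) {
            out_pool <- setdiff(seq_len(ncp), child[[j]])
            if (length(out_pool) > 0L) {
              drop_at <- sample.int(sizes[j], 1L)
              child[[j]][drop_at] <- out_pool[sample.int(length(out_pool), 1L)]
            }
          }
        }
        newpop[[length(newpop) + 1L]] <- child
        newfit <- c(newfit, fitness(child))
      }
      pop <- newpop
      fit <- newfit
      gen_best <- which.max(fit)
      if (fit[gen_best] > best_fit + 1e-12) {
        best_fit <- fit[gen_best]
        best <- pop[[gen_best]]
        streak <- 0L
      } else {
        streak <- streak + 1L
      }
      trace[iter] <- best_fit
      if (iter >= cfg$min_iterations && streak >= cfg$patience) break
    }
    list(best = best, best_fit = best_fit, trace = trace, iter = iter)
  })

  structure(list(best_design = training_design(lapply(res$best, sort), ncp = ncp),
                 best_score = res$best_fit,
                 trace = res$trace,
                 iterations_run = res$iter,
                 seed = cfg$seed),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat("optimization_result: best score", format(x$best_score, digits = 6),
      "after", x$iterations_run, "iterations\n")
  invisible(x)
}
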