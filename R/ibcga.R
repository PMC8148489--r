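#' Hyperparameter level grid for the 4-bit chromosome codes
#'
#' Each nu-SVR hyperparameter is encoded by a 4-bit gene indexing one of
#' 16 levels. Defaults follow the libsvm grid-search convention:
#' gamma and C over 16 powers of two (2^-7 .. 2^8), nu over
#' 1/16 .. 16/16.
#'
#' @param gamma_levels,cost_levels,nu_levels 16 strictly increasing
#'   positive values each; nu levels must lie in (0, 1]
#' @return a `param_grid`
#' @export
param_grid <- function(gamma_levels = 2^seq(-7, 8),
                       cost_levels = 2^seq(-7, 8),
                       nu_levels = (1:16) / 16) {
  check_levels <- function(v, name) {
    if (length(v) != 16 || any(v <= 0) || any(diff(v) <= 0)) {
      stop(name, " must be 16 strictly increasing positive values")
    }
  }
  check_levels(gamma_levels, "gamma_levels")
  check_levels(cost_levels, "cost_levels")
  check_levels(nu_levels, "nu_levels")
  if (any(nu_levels > 1)) stop("nu levels must be <= 1")
  structure(list(gamma_levels = gamma_levels, cost_levels = cost_levels,
                 nu_levels = nu_levels),
            class = "param_grid")
}

#' GA configuration
#'
#' @param n_pop population size (even, >= 4)
#' @param r_start initial feature budget
#' @param r_end final feature budget
#' @param generations_per_r generation budget per feature budget r
#' @param stagnation_patience end a budget phase early after this many
#'   generations without improvement of the phase best
#' @param crossover_rate probability a selected pair undergoes
#'   orthogonal-array crossover
#' @param mutation_rate per-bit flip probability for parameter genes and
#'   per-individual swap probability for feature genes
#' @param oa_max_factors cap on orthogonal-array factors per crossover
#'   (differing genes are grouped when they exceed it)
#' @param k_folds folds for the cross-validated fitness
#' @param seed integer master seed; the full run is deterministic given it
#' @return a `ga_config`
#' @export
ga_config <- function(n_pop = 50, r_start = 50, r_end = 10,
                      generations_per_r = 30, stagnation_patience = 10,
                      crossover_rate = 0.8, mutation_rate = 0.05,
                      oa_max_factors = 7, k_folds = 10, seed = 1L) {
  stopifnot(n_pop >= 4, n_pop %% 2 == 0,
            r_end >= 1, r_end <= r_start,
            generations_per_r >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            oa_max_factors >= 1)
  structure(list(n_pop = as.integer(n_pop),
                 r_start = as.integer(r_start), r_end = as.integer(r_end),
                 generations_per_r = as.integer(generations_per_r),
                 stagnation_patience = as.integer(stagnation_patience),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 oa_max_factors = as.integer(oa_max_factors),
                 k_folds = as.integer(k_folds),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# A chromosome is d binary feature genes plus three 4-bit codes (0..15)
# selecting gamma, C and nu levels.
chromosome <- function(features, params) {
  stopifnot(all(features %in% c(0L, 1L)), length(params) == 3,
            all(params >= 0), all(params <= 15))
  list(features = as.integer(features), params = as.integer(params))
}

chrom_key <- function(chrom) {
  paste(c(which(chrom$features == 1L), "|", chrom$params), collapse = ",")
}

#' Decode a chromosome's 4-bit parameter genes
#'
#' @param chrom a chromosome (list with `features`, `params`)
#' @param grid a [param_grid()]
#' @return an [svr_config()]
#' @export
decode_params <- function(chrom, grid) {
  svr_config(gamma = grid$gamma_levels[chrom$params[1] + 1L],
             cost = grid$cost_levels[chrom$params[2] + 1L],
             nu = grid$nu_levels[chrom$params[3] + 1L])
}

#' Random initial population at the starting feature budget
#'
#' Each individual gets exactly `r_start` uniformly random set feature
#' genes and uniform random 4-bit parameter codes. Uses the current RNG
#' stream (seed at the [run_ibcga()] level).
#'
#' @param cfg a [ga_config()]
#' @param d total feature count
#' @return list of chromosomes
#' @export
initialize_population <- function(cfg, d) {
  if (cfg$r_start > d) stop("r_start (", cfg$r_start,
                            ") exceeds feature count (", d, ")")
  lapply(seq_len(cfg$n_pop), function(i) {
    feats <- integer(d)
    feats[sample.int(d, cfg$r_start)] <- 1L
    chromosome(feats, sample.int(16, 3) - 1L)
  })
}

#' Binary tournament selection
#'
#' Draws `length(population)` independent size-2 tournaments (with
#' replacement); the individual with higher CC wins, ties broken by
#' lower MAE, then by earlier population position.
#'
#' @param population list of chromosomes
#' @param fitnesses list of `fitness_result`, parallel to `population`
#' @return list of winning chromosomes (the mating pool)
#' @export
tournament_select <- function(population, fitnesses) {
  n <- length(population)
  pool <- vector("list", n)
  for (i in seq_len(n)) {
    a <- sample.int(n, 1)
    b <- sample.int(n, 1)
    win <- if (a == b) a
           else if (fitness_better(fitnesses[[b]], fitnesses[[a]])) b
           else a
    pool[[i]] <- population[[win]]
  }
  pool
}

# Restore popcount(features) == r by randomly clearing surplus set bits
# or setting random unset bits. Uses the current RNG stream.
repair_budget <- function(features, r) {
  pc <- sum(features)
  while (pc > r) {
    set_pos <- which(features == 1L)
    features[set_pos[sample.int(length(set_pos), 1)]] <- 0L
    pc <- pc - 1L
  }
  while (pc < r) {
    unset_pos <- which(features == 0L)
    features[unset_pos[sample.int(length(unset_pos), 1)]] <- 1L
    pc <- pc + 1L
  }
  features
}

# Compose a candidate from parent 1, taking the genes of factors at
# level 2 from parent 2. `factors` is a list of gene descriptors
# (list(type = "feature"/"param", pos)).
compose_candidate <- function(p1, p2, factors, levels_, r) {
  feats <- p1$features
  params <- p1$params
  for (fi in seq_along(factors)) {
    if (levels_[fi] == 2L) {
      for (g in factors[[fi]]) {
        if (g$type == "feature") feats[g$pos] <- p2$features[g$pos]
        else params[g$pos] <- p2$params[g$pos]
      }
    }
  }
  feats <- repair_budget(feats, r)
  chromosome(feats, params)
}

#' Orthogonal-array crossover
#'
#' The genes where the parents differ (feature genes and parameter
#' genes) are grouped into at most `max_factors` factors; a two-level
#' orthogonal array assigns each factor to parent 1 (level 1) or parent
#' 2 (level 2) per run. Every run's candidate is repaired to the
#' feature budget `r` and evaluated. Each factor's main effect
#' difference on the CC response picks the better parent per factor for
#' `child1`; `child2` is the best evaluated run candidate.
#'
#' @param p1,p2 parent chromosomes at budget r
#' @param eval_fn function(chromosome) -> `fitness_result`
#' @param r current feature budget
#' @param max_factors factor cap (default 7, i.e. an 8-run array)
#' @return list with `child1`, `child2`, their fitnesses, and the
#'   evaluated OA candidates (`oa_candidates`, `oa_fitnesses`)
#' @export
orthogonal_array_crossover <- function(p1, p2, eval_fn, r,
                                       max_factors = 7) {
  diff_feat <- which(p1$features != p2$features)
  diff_par <- which(p1$params != p2$params)
  genes <- c(lapply(diff_feat, function(p) list(type = "feature", pos = p)),
             lapply(diff_par, function(p) list(type = "param", pos = p)))
  if (length(genes) == 0) {
    return(list(child1 = p1, child2 = p2,
                child1_fitness = NULL, child2_fitness = NULL,
                oa_candidates = list(), oa_fitnesses = list()))
  }
  n_genes <- length(genes)
  n_fac <- min(n_genes, max_factors)
  order_ <- sample.int(n_genes)
  grouping <- rep_len(seq_len(n_fac), n_genes)
  factors <- split(genes[order_], grouping)

  oa <- oa_two_level(n_fac)
  cands <- vector("list", nrow(oa))
  fits <- vector("list", nrow(oa))
  for (i in seq_len(nrow(oa))) {
    cands[[i]] <- compose_candidate(p1, p2, factors, oa[i, ], r)
    fits[[i]] <- eval_fn(cands[[i]])
  }
  cc <- vapply(fits, function(f) f$cc, numeric(1))

  # main effect difference per factor on the CC response
  best_levels <- integer(n_fac)
  for (fi in seq_len(n_fac)) {
    m1 <- mean(cc[oa[, fi] == 1L])
    m2 <- mean(cc[oa[, fi] == 2L])
    best_levels[fi] <- if (m2 > m1) 2L else 1L
  }
  child1 <- compose_candidate(p1, p2, factors, best_levels, r)
  child1_fit <- eval_fn(child1)
  best_row <- which_best(fits)
  list(child1 = child1, child2 = cands[[best_row]],
       child1_fitness = child1_fit, child2_fitness = fits[[best_row]],
       oa_candidates = cands, oa_fitnesses = fits)
}

#' Mutate a chromosome, preserving the feature budget
#'
#' Parameter genes: each of the 12 bits flips independently with
#' `mutation_rate`. Feature genes: with probability `mutation_rate`,
#' one random set bit exchanges values with a uniformly chosen position
#' (popcount preserved; drawing the same or another set position is a
#' no-op). The elite individual is returned unchanged.
#'
#' @param chrom chromosome
#' @param is_elite exempt from mutation (elitism)
#' @param mutation_rate probability, see above
#' @return mutated chromosome
#' @export
mutate_chromosome <- function(chrom, is_elite = FALSE,
                              mutation_rate = 0.05) {
  if (is_elite) return(chrom)
  params <- chrom$params
  for (slot in 1:3) {
    for (bit in 0:3) {
      if (stats::runif(1) < mutation_rate) {
        params[slot] <- bitwXor(params[slot], bitwShiftL(1L, bit))
      }
    }
  }
  feats <- chrom$features
  if (stats::runif(1) < mutation_rate) {
    set_pos <- which(feats == 1L)
    if (length(set_pos) > 0) {
      i <- set_pos[sample.int(length(set_pos), 1)]
      j <- sample.int(length(feats), 1)  # any position; i == j is a no-op
      tmp <- feats[i]; feats[i] <- feats[j]; feats[j] <- tmp
    }
  }
  chromosome(feats, params)
}

#' Inheritance step: drop one feature from every individual
#'
#' Each individual has one uniformly chosen set feature gene cleared,
#' taking the whole population from budget r to r - 1. Parameter genes
#' are untouched.
#'
#' @param population list of chromosomes at budget r > r_end
#' @return population at budget r - 1
#' @export
inherit_population <- function(population) {
  lapply(population, function(ch) {
    set_pos <- which(ch$features == 1L)
    if (length(set_pos) <= 1) stop("cannot inherit below 1 feature")
    ch$features[set_pos[sample.int(length(set_pos), 1)]] <- 0L
    ch
  })
}

#' Run the inheritable bi-objective combinatorial GA
#'
#' Sweeps the feature budget from `r_start` down to `r_end`. At each
#' budget r the population evolves by 10-CV-fitness evaluation,
#' binary tournament selection, orthogonal-array crossover, and swap /
#' bit mutation with elitism, for at most `generations_per_r`
#' generations (early stop on `stagnation_patience` stagnant
#' generations); the phase best is recorded as the solution X_r, then
#' every individual inherits by losing one feature. The overall best
#' X_m across budgets is the selected signature. One fold partition
#' (derived from the master seed) is shared by every fitness
#' evaluation of the run, so chromosomes are compared on identical
#' folds. Fully deterministic given `cfg$seed`.
#'
#' @param dataset a `survival_dataset`
#' @param cfg a [ga_config()]
#' @param grid a [param_grid()]
#' @param eval_hook optional function(chromosome, r, fitness) called
#'   after every fitness evaluation (instrumentation; must not modify)
#' @param verbose log per-phase progress
#' @return a `solution_set`: `per_r_best` (list keyed by r of
#'   chromosome + fitness), `overall_best` (X_m with decoded
#'   hyperparameters and selected feature names), `history`
#'   (per-generation best-fitness trace), `folds`, `cfg`
#' @export
run_ibcga <- function(dataset, cfg, grid = param_grid(),
                      eval_hook = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "ga_config"))
  d <- length(dataset$cohort$feature_names)
  n <- length(dataset$survival_years)
  with_seed(cfg$seed, {
    folds <- make_folds(n, cfg$k_folds, seed = NULL)
    cache <- new.env(parent = emptyenv())
    r_cur <- cfg$r_start

    eval_chrom <- function(chrom) {
      key <- chrom_key(chrom)
      hit <- get0(key, envir = cache, inherits = FALSE)
      if (!is.null(hit)) return(hit)
      fit <- cv_fitness(dataset, chrom$features,
                        decode_params(chrom, grid), folds = folds)
      assign(key, fit, envir = cache)
      if (!is.null(eval_hook)) eval_hook(chrom, r_cur, fit)
      fit
    }

    pop <- initialize_population(cfg, d)
    per_r_best <- list()
    history <- list()

    for (r in seq(cfg$r_start, cfg$r_end, by = -1)) {
      r_cur <- r
      fits <- lapply(pop, eval_chrom)
      best_i <- which_best(fits)
      best <- list(chrom = pop[[best_i]], fitness = fits[[best_i]])
      stagnant <- 0L
      for (gen in seq_len(cfg$generations_per_r)) {
        pool <- tournament_select(pop, fits)
        new_pop <- vector("list", cfg$n_pop)
        for (i in seq(1, cfg$n_pop, by = 2)) {
          pa <- pool[[i]]; pb <- pool[[i + 1]]
          if (stats::runif(1) < cfg$crossover_rate) {
            cx <- orthogonal_array_crossover(pa, pb, eval_chrom, r,
                                             cfg$oa_max_factors)
            new_pop[[i]] <- cx$child1
            new_pop[[i + 1]] <- cx$child2
          } else {
            new_pop[[i]] <- pa
            new_pop[[i + 1]] <- pb
          }
        }
        # elitism: the phase best survives untouched in slot 1
        new_pop[[1]] <- best$chrom
        new_pop[2:cfg$n_pop] <- lapply(new_pop[2:cfg$n_pop],
                                       mutate_chromosome,
                                       is_elite = FALSE,
                                       mutation_rate = cfg$mutation_rate)
        pop <- new_pop
        fits <- lapply(pop, eval_chrom)
        gen_best_i <- which_best(fits)
        if (fitness_better(fits[[gen_best_i]], best$fitness)) {
          best <- list(chrom = pop[[gen_best_i]],
                       fitness = fits[[gen_best_i]])
          stagnant <- 0L
        } else {
          stagnant <- stagnant + 1L
        }
        history[[length(history) + 1]] <-
          list(r = r, generation = gen, best_cc = best$fitness$cc,
               best_mae = best$fitness$mae_years)
        if (stagnant >= cfg$stagnation_patience) break
      }
      per_r_best[[as.character(r)]] <- best
      if (verbose) {
        message(sprintf("budget r=%d: CC=%.4f MAE=%.4f", r,
                        best$fitness$cc, best$fitness$mae_years))
      }
      if (r > cfg$r_end) pop <- inherit_population(pop)
    }

    best_r_i <- which_best(lapply(per_r_best, `[[`, "fitness"))
    overall <- per_r_best[[best_r_i]]
    sel <- which(overall$chrom$features == 1L)
    structure(list(
      per_r_best = per_r_best,
      overall_best = list(
        r = as.integer(names(per_r_best)[best_r_i]),
        chrom = overall$chrom,
        fitness = overall$fitness,
        features = dataset$cohort$feature_names[sel],
        svr_config = decode_params(overall$chrom, grid)),
      history = do.call(rbind, lapply(history, as.data.frame)),
      folds = folds,
      cfg = cfg),
      class = "solution_set")
  })
}

#' @exportS3Method base::print
print.solution_set <- function(x, ...) {
  ob <- x$overall_best
  cat(sprintf(paste0("<solution_set> budgets %s..%s; best r = %d ",
                     "(CC = %.4f, MAE = %.4f years)\n"),
              x$cfg$r_start, x$cfg$r_end, ob$r,
              ob$fitness$cc, ob$fitness$mae_years))
  invisible(x)
}

#' Multi-run aggregate of the GA
#'
#' Repeats [run_ibcga()] with distinct seeds derived from `base_seed`
#' and reports per-run CC / MAE / signature size, their mean and SD,
#' and the per-feature selection frequency across runs (the multi-run
#' mean row of the method's comparison table).
#'
#' @param dataset a `survival_dataset`
#' @param cfg a [ga_config()]; its seed field is replaced per run
#' @param grid a [param_grid()]
#' @param n_runs number of independent runs (>= 2; default 10)
#' @param base_seed run i uses seed `base_seed + i - 1`
#' @return an `ibcga_replicates` list: `runs` data frame (seed, r, cc,
#'   mae_years), `mean_cc`, `sd_cc`, `mean_mae`, `sd_mae`,
#'   `mean_n_selected`, `selection_frequency` (named vector), and the
#'   per-run solution sets
#' @export
run_ibcga_replicates <- function(dataset, cfg, grid = param_grid(),
                                 n_runs = 10, base_seed = cfg$seed) {
  stopifnot(n_runs >= 2)
  seeds <- base_seed + seq_len(n_runs) - 1L
  sols <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(seeds[i])
    sols[[i]] <- run_ibcga(dataset, cfg_i, grid)
  }
  runs <- data.frame(
    seed = seeds,
    r = vapply(sols, function(s) s$overall_best$r, integer(1)),
    cc = vapply(sols, function(s) s$overall_best$fitness$cc, numeric(1)),
    mae_years = vapply(sols, function(s) s$overall_best$fitness$mae_years,
                       numeric(1)))
  feat_names <- dataset$cohort$feature_names
  counts <- setNames(numeric(length(feat_names)), feat_names)
  for (s in sols) counts[s$overall_best$features] <-
    counts[s$overall_best$features] + 1
  structure(list(runs = runs,
                 mean_cc = mean(runs$cc), sd_cc = stats::sd(runs$cc),
                 mean_mae = mean(runs$mae_years),
                 sd_mae = stats::sd(runs$mae_years),
                 mean_n_selected = mean(runs$r),
                 selection_frequency = counts / n_runs,
                 solutions = sols),
            class = "ibcga_replicates")
}

#' @exportS3Method base::print
print.ibcga_replicates <- function(x, ...) {
  cat(sprintf(paste0("<ibcga_replicates> %d runs: CC = %.3f+-%.3f, ",
                     "MAE = %.3f+-%.3f years, mean signature size %.2f\n"),
              nrow(x$runs), x$mean_cc, x$sd_cc, x$mean_mae, x$sd_mae,
              x$mean_n_selected))
  invisible(x)
}
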