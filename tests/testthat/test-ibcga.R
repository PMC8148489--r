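test_that("the two-level orthogonal array is balanced and orthogonal", {
  for (f in c(1, 3, 4, 7, 12)) {
    oa <- oa_two_level(f)
    expect_equal(ncol(oa), f)
    expect_true(nrow(oa) >= f + 1)
    expect_true(all(oa %in% 1:2))
    # balance per column
    for (j in seq_len(f)) expect_equal(sum(oa[, j] == 1), nrow(oa) / 2)
    # pairwise orthogonality: each level pair appears equally often
    if (f >= 2) {
      for (j in 2:f) {
        tab <- table(oa[, 1], oa[, j])
        expect_true(all(tab == nrow(oa) / 4))
      }
    }
  }
})

test_that("parameter genes decode through the level grid", {
  grid <- param_grid()
  ch_lo <- list(features = rep(1L, 4), params = c(0L, 0L, 0L))
  ch_hi <- list(features = rep(1L, 4), params = c(15L, 15L, 15L))
  lo <- decode_params(ch_lo, grid); hi <- decode_params(ch_hi, grid)
  expect_equal(lo$gamma, 2^-7); expect_equal(hi$gamma, 2^8)
  expect_equal(lo$cost, 2^-7); expect_equal(hi$cost, 2^8)
  expect_equal(lo$nu, 1 / 16); expect_equal(hi$nu, 1)
  for (code in 0:15) {
    nu <- decode_params(list(features = 1L, params = c(0L, 0L, code)),
                        grid)$nu
    expect_true(nu > 0 && nu <= 1)
  }
})

test_that("initial populations have exact budgets and seeded determinism", {
  cfg <- ga_config(n_pop = 30, r_start = 12, r_end = 5, seed = 1)
  set.seed(100); pop1 <- initialize_population(cfg, d = 40)
  set.seed(100); pop2 <- initialize_population(cfg, d = 40)
  set.seed(101); pop3 <- initialize_population(cfg, d = 40)
  expect_identical(pop1, pop2)
  expect_false(identical(pop1, pop3))
  expect_true(all(vapply(pop1, function(c) sum(c$features), numeric(1)) == 12))
  expect_error(initialize_population(cfg, d = 10), "exceeds")

  # bit frequency roughly uniform at r_start/d per position
  cfg_big <- ga_config(n_pop = 1000, r_start = 12, r_end = 5, seed = 1)
  set.seed(7)
  freq <- colMeans(do.call(rbind, lapply(initialize_population(cfg_big, 40),
                                         `[[`, "features")))
  chi2 <- sum((freq * 1000 - 300)^2 / 300)  # E = 1000 * 12/40
  expect_lt(chi2, qchisq(1 - 1e-6, df = 39))
})

test_that("tournament selection favours the fitter individual", {
  pop <- list(list(features = c(1L, 0L), params = c(0L, 0L, 0L)),
              list(features = c(0L, 1L), params = c(1L, 1L, 1L)))
  fits <- list(list(cc = 0.9, mae_years = 1), list(cc = 0.1, mae_years = 1))
  set.seed(50)
  picked <- replicate(5000, {
    pool <- tournament_select(pop, fits)
    mean(vapply(pool, function(c) c$features[1] == 1L, logical(1)))
  })
  # each slot: better individual wins unless the weaker is drawn twice
  expect_equal(mean(picked), 0.75, tolerance = 0.02)

  # all-equal fitness: composition is symmetric
  fits_eq <- list(list(cc = 0.5, mae_years = 1), list(cc = 0.5, mae_years = 1))
  picked_eq <- replicate(5000, {
    pool <- tournament_select(pop, fits_eq)
    mean(vapply(pool, function(c) c$features[1] == 1L, logical(1)))
  })
  expect_equal(mean(picked_eq), 0.5, tolerance = 0.02)

  # ties on CC break by lower MAE
  fits_mae <- list(list(cc = 0.5, mae_years = 2), list(cc = 0.5, mae_years = 1))
  pool <- tournament_select(pop, fits_mae)
  expect_true(any(vapply(pool, function(c) c$features[2] == 1L, logical(1))))
})

test_that("swap mutation preserves budget and spares the elite", {
  set.seed(60)
  ch <- list(features = c(1L, 0L, 1L, 0L, 1L, 0L, 0L, 1L),
             params = c(3L, 9L, 15L))
  expect_identical(mutate_chromosome(ch, is_elite = TRUE, 1.0), ch)
  for (i in 1:50) {
    m <- mutate_chromosome(ch, is_elite = FALSE, mutation_rate = 0.5)
    expect_equal(sum(m$features), 4)
    expect_true(all(m$params >= 0 & m$params <= 15))
  }
  # single set bit of 10 moves with probability 9/10 at rate 1
  ch1 <- list(features = c(1L, rep(0L, 9)), params = c(0L, 0L, 0L))
  moved <- replicate(4000, {
    mutate_chromosome(ch1, FALSE, 1.0)$features[1] == 0L
  })
  expect_equal(mean(moved), 0.9, tolerance = 0.03)
})

test_that("inheritance removes exactly one feature per individual", {
  set.seed(70)
  cfg <- ga_config(n_pop = 40, r_start = 10, r_end = 2, seed = 1)
  pop <- initialize_population(cfg, d = 30)
  inh <- inherit_population(pop)
  for (i in seq_along(pop)) {
    expect_equal(sum(inh[[i]]$features), 9)
    # only clearances, never new set bits; params untouched
    expect_true(all(inh[[i]]$features <= pop[[i]]$features))
    expect_identical(inh[[i]]$params, pop[[i]]$params)
  }
  # cleared position roughly uniform over the r set bits
  ch <- list(features = c(rep(1L, 5), rep(0L, 5)), params = c(0L, 0L, 0L))
  cleared <- replicate(5000, which(inherit_population(list(ch))[[1]]$features
                                   < ch$features))
  expect_equal(unname(prop.table(table(cleared))), rep(0.2, 5),
               tolerance = 0.1, ignore_attr = TRUE)
})

test_that("OA crossover matches exhaustive enumeration on small gene sets", {
  set.seed(80)
  d <- 12; r <- 4
  weights <- runif(d, -1, 1)
  eval_fn <- toy_eval_fn(weights)
  for (trial in 1:20) {
    # build two parents at budget r differing in <= 4 genes
    base <- integer(d); base[sample.int(d, r)] <- 1L
    f2 <- base
    on_bit <- sample(which(base == 1L), 1)
    off_bit <- sample(which(base == 0L), 1)
    f2[on_bit] <- 0L; f2[off_bit] <- 1L
    params <- sample(0:15, 3, replace = TRUE)
    p1 <- list(features = base, params = as.integer(params))
    p2_params <- as.integer(params)
    p2_params[1] <- bitwXor(p2_params[1], 1L)  # one differing param gene
    p2 <- list(features = f2, params = p2_params)

    cx <- orthogonal_array_crossover(p1, p2, eval_fn, r)
    expect_equal(sum(cx$child1$features), r)
    expect_equal(sum(cx$child2$features), r)
    # child2 is the best of the evaluated OA candidates
    ccs <- vapply(cx$oa_fitnesses, `[[`, numeric(1), "cc")
    expect_equal(eval_fn(cx$child2)$cc, max(ccs), tolerance = 1e-12)
    # and no enumerated assignment of the differing genes beats it by
    # more than the toy fitness range of one gene (OA evaluates a
    # half-fraction; its best must be within the enumerated set)
    expect_true(eval_fn(cx$child2)$cc %in% ccs)
  }

  # identical parents short-circuit
  p <- list(features = base, params = as.integer(params))
  same <- orthogonal_array_crossover(p, p, eval_fn, r)
  expect_identical(same$child1, p)
  expect_identical(same$child2, p)
})

test_that("a small GA run honours budgets, elitism and determinism", {
  sim <- tiny_sim(n = 40, d = 16, k = 3, noise_sd = 0.2, seed = 2)
  cfg <- ga_config(n_pop = 8, r_start = 7, r_end = 4,
                   generations_per_r = 4, stagnation_patience = 3,
                   k_folds = 5, seed = 21)
  budgets_seen <- new.env(); budgets_seen$ok <- TRUE; budgets_seen$rs <- c()
  hook <- function(chrom, r, fit) {
    budgets_seen$ok <- budgets_seen$ok && (sum(chrom$features) == r)
    budgets_seen$rs <- union(budgets_seen$rs, r)
  }
  sol <- run_ibcga(sim$dataset, cfg, eval_hook = hook)
  expect_true(budgets_seen$ok)
  expect_setequal(budgets_seen$rs, 7:4)
  expect_equal(as.integer(names(sol$per_r_best)), 7:4)
  expect_equal(length(sol$per_r_best), 7 - 4 + 1)

  # best-so-far trace non-decreasing within each budget phase
  for (r in 7:4) {
    tr <- sol$history$best_cc[sol$history$r == r]
    expect_true(all(diff(tr) >= -1e-12))
  }
  # overall best equals the max over per-r solutions
  ccs <- vapply(sol$per_r_best, function(b) b$fitness$cc, numeric(1))
  expect_equal(sol$overall_best$fitness$cc, max(ccs))

  sol2 <- run_ibcga(sim$dataset, cfg)
  expect_identical(sol2$overall_best$chrom, sol$overall_best$chrom)
  expect_identical(sol2$history, sol$history)
})

test_that("replicated runs aggregate means and selection frequencies", {
  sim <- tiny_sim(n = 30, d = 10, k = 2, noise_sd = 0.2, seed = 4)
  cfg <- ga_config(n_pop = 6, r_start = 4, r_end = 3,
                   generations_per_r = 2, stagnation_patience = 2,
                   k_folds = 5, seed = 100)
  agg <- run_ibcga_replicates(sim$dataset, cfg, n_runs = 3)
  expect_equal(nrow(agg$runs), 3)
  expect_equal(agg$runs$seed, c(100, 101, 102))
  expect_equal(agg$mean_cc, mean(agg$runs$cc))
  expect_equal(agg$sd_mae, sd(agg$runs$mae_years))
  expect_equal(agg$mean_n_selected, mean(agg$runs$r))
  expect_true(all(agg$selection_frequency >= 0 &
                    agg$selection_frequency <= 1))
})
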