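test_that("policy distribution is normalized and uniform for zero output weights", {
  params <- init_policy_params(4, c("A", "C", "D", "E", "G"), d_emb = 6, d_h = 8,
                               seed = 1)
  p <- policy_distribution(params, c("A", "C", "D", "E"))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  params$Wout <- params$Wout * 0
  params$bout <- params$bout * 0
  p0 <- policy_distribution(params, c("A", "C", "D", "E"))
  expect_equal(p0, rep(1 / 20, 20), tolerance = 1e-12)
})

test_that("relabeling the alphabet with matching parameter permutation commutes", {
  al <- c("A", "C", "D", "E")
  params <- init_policy_params(3, al, d_emb = 5, d_h = 6, seed = 2)
  perm <- c(3L, 1L, 4L, 2L)            # new index of each old letter
  params2 <- params
  params2$E[perm, ] <- params$E
  A <- length(al); n <- 3
  idx_map <- as.vector(vapply(seq_len(n), function(i) (i - 1L) * A + perm,
                              integer(A)))
  params2$Wout[idx_map, ] <- params$Wout
  params2$bout[idx_map] <- params$bout
  s <- c("A", "D", "C")
  relabeled <- al[perm][match(s, al)]
  p1 <- policy_distribution(params, s)
  p2 <- policy_distribution(params2, relabeled)
  expect_equal(p2[idx_map], p1, tolerance = 1e-9)
})

test_that("actions update sequences commutatively and reward is minus the score change", {
  al <- default_alphabet()
  s <- rep("A", 6)
  s2 <- apply_action(s, 4, "W", al)
  expect_identical(which(s2 != s), 4L)
  expect_identical(apply_action(s, 2, "A", al), s)
  ab <- apply_action(apply_action(s, 2, "K", al), 5, "D", al)
  ba <- apply_action(apply_action(s, 5, "D", al), 2, "K", al)
  expect_identical(ab, ba)
  expect_error(apply_action(s, 9, "A", al), class = "pottspep_usage_error")

  tb <- make_random_tables(4, c("A", "C", "D", "E"), scale = 1, seed = 5)
  m <- potts_model(tb)
  s0 <- c("A", "C", "D", "E")
  s1 <- apply_action(s0, 2, "E", tb$alphabet)
  expect_equal(step_reward(m, s0, s1),
               potts_score(m, s0) - potts_score(m, s1), tolerance = 1e-12)
  expect_identical(step_reward(m, s0, s0), 0)
})

test_that("episode rewards telescope to the net score drop", {
  tb <- make_random_tables(4, c("A", "C", "D", "E"), scale = 1, seed = 6)
  m <- potts_model(tb)
  s <- c("A", "A", "A", "A")
  total <- 0
  set.seed(3)
  cur <- s
  for (k in 1:15) {
    nxt <- apply_action(cur, sample(4, 1), sample(tb$alphabet, 1), tb$alphabet)
    total <- total + step_reward(m, cur, nxt)
    cur <- nxt
  }
  expect_equal(total, potts_score(m, s) - potts_score(m, cur), tolerance = 1e-9)
})

test_that("hand-derived policy gradients match numerical differentiation", {
  n <- 3; A <- 4
  params <- init_policy_params(n, c("A", "C", "D", "E"), d_emb = 3, d_h = 4,
                               seed = 42)
  idx <- c(1L, 3L, 2L)
  act <- 5L
  loss <- function(p) {
    fw <- pottspep:::policy_forward(p, idx)
    -log(fw$probs[act]) + 0.5 * (fw$v - 1)^2
  }
  fw <- pottspep:::policy_forward(params, idx)
  ea <- numeric(n * A); ea[act] <- 1
  gr <- pottspep:::policy_backward(params, fw, -(ea - fw$probs), fw$v - 1)
  h <- 1e-6
  for (nm in pottspep:::ppo_param_names()) {
    for (k in seq_len(min(length(params[[nm]]), 5))) {
      p2 <- params
      p2[[nm]][k] <- p2[[nm]][k] + h
      num <- (loss(p2) - loss(params)) / h
      expect_equal(gr[[nm]][k], num, tolerance = 1e-3,
                   label = sprintf("grad %s[%d]", nm, k))
    }
  }
})

test_that("PPO raises the probability of the one rewarded action (bandit)", {
  # environment: fixed state, action 3 always earns +1, the rest 0
  env <- list(reset = function() c(1L, 1L),
              step = function(idx, a)
                list(state = idx, reward = if (a == 3L) 1 else 0))
  cfg <- ppo_config(d_emb = 4, d_h = 8, horizon = 8, episodes_per_update = 4,
                    updates = 25, epochs = 3, learning_rate = 2e-2,
                    kl_limit = Inf, seed = 7)
  out <- pottspep:::ppo_train_env(env, n = 2, A = 3, cfg)
  p_start <- pottspep:::policy_forward(
    init_policy_params(2, c("A", "C", "D"), d_emb = 4, d_h = 8,
                       seed = pottspep:::child_seed(7, 1)), c(1L, 1L))$probs[3]
  p_end <- pottspep:::policy_forward(out$params, c(1L, 1L))$probs[3]
  expect_gt(p_end, p_start)
  expect_gt(p_end, 0.5)
})

test_that("training is deterministic per seed and lowers scores on planted tables", {
  tb <- make_planted_tables(4, c("A", "C", "D", "E", "G"), gap = 4, seed = 11)
  m <- potts_model(tb)
  start <- c("E", "E", "E", "E")
  cfg <- ppo_config(d_emb = 6, d_h = 12, horizon = 10, episodes_per_update = 3,
                    updates = 8, seed = 9)
  run1 <- ppo_train(m, start, cfg)
  run2 <- ppo_train(m, start, cfg)
  expect_identical(run1$log, run2$log)
  # later updates collect more reward (descend the landscape) than early ones
  lg <- run1$log
  expect_gt(mean(lg$mean_reward[-(1:2)]), min(lg$mean_reward[1:2]) - 1e-9)
  expect_true(all(is.finite(lg$loss)))
})

test_that("alternate harvesting respects the window, excludes the seed, dedups", {
  dg <- make_degenerate_tables(4, c("A", "C", "D", "E", "G"), k_alternates = 8,
                               window = 5, seed = 19)
  m <- potts_model(dg)
  seedseq <- attr(dg, "planted")
  cfg <- ppo_config(d_emb = 6, d_h = 16, horizon = 15, episodes_per_update = 3,
                    updates = 6, seed = 21)
  pol <- ppo_train(m, seedseq, cfg)
  alts <- collect_alternates(pol, m, window = 5, budget = 4000, seed = 22)
  expect_gt(length(alts$members), 0L)
  best <- potts_score(m, seedseq)
  keys <- vapply(alts$members, function(x) paste(x$sequence, collapse = ""), "")
  expect_identical(anyDuplicated(keys), 0L)
  expect_false(paste(seedseq, collapse = "") %in% keys)
  for (mb in alts$members) {
    expect_lte(mb$score, best + 5 + 1e-9)
    expect_equal(potts_score(m, mb$sequence), mb$score, tolerance = 1e-9)
  }
  # window 0 on a unique-optimum landscape yields nothing
  pt <- make_planted_tables(4, c("A", "C", "D", "E", "G"), gap = 3, seed = 23)
  mp <- potts_model(pt)
  polp <- ppo_train(mp, attr(pt, "planted"), cfg)
  none <- collect_alternates(polp, mp, window = 0, budget = 2000, seed = 24)
  expect_length(none$members, 0L)
})

test_that("seeding exploration from the optimum beats a random seed sequence", {
  al <- c("A", "C", "D", "E", "G", "K", "R", "S")
  dg <- make_degenerate_tables(8, al, k_alternates = 10, window = 5, seed = 33,
                               verify = FALSE)
  m <- potts_model(dg)
  cfg <- ppo_config(d_emb = 6, d_h = 16, horizon = 15, episodes_per_update = 3,
                    updates = 6, seed = 34)
  best <- potts_score(m, attr(dg, "planted"))
  pol_opt <- ppo_train(m, attr(dg, "planted"), cfg)
  n_opt <- length(collect_alternates(pol_opt, m, best_score = best, window = 5,
                                     budget = 3000, seed = 35)$members)
  rnd <- random_sequence(8, al, seed = 36)
  pol_rnd <- ppo_train(m, rnd, cfg)
  n_rnd <- length(collect_alternates(pol_rnd, m, seed_sequence = rnd,
                                     best_score = best, window = 5,
                                     budget = 3000, seed = 35)$members)
  expect_gt(n_opt, n_rnd)
})
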