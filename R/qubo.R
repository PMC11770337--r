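#' Solve result container
#'
#' @param sequence character vector of residues.
#' @param score Potts score of `sequence` (kcal/mol).
#' @param method solver name.
#' @param seed integer seed used (NA for deterministic solvers).
#' @param metadata named list of provenance (schedule, lambda, penalty, ...).
#' @return object of class `solve_result`.
#' @export
solve_result <- function(sequence, score, method, seed = NA_integer_, metadata = list()) {
  structure(list(sequence = sequence, score = score, method = method,
                 seed = seed, metadata = metadata), class = "solve_result")
}

#' @export
print.solve_result <- function(x, ...) {
  cat(sprintf("[%s] %s  score = %.6g\n", x$method, seq_key(x$sequence), x$score))
  invisible(x)
}

# Decode chunk of lexicographic codes (0-based) into an index matrix
# (rows = sequences, columns = residues, values = 1-based alphabet indices).
# Position 1 is the most significant digit so code order == lexicographic order.
codes_to_idx <- function(codes, n, A) {
  m <- matrix(0L, length(codes), n)
  rem <- codes
  for (k in n:1) {
    m[, k] <- as.integer(rem %% A) + 1L
    rem <- rem %/% A
  }
  m
}

score_idx_matrix <- function(model, M) {
  tb <- model$tables
  s <- numeric(nrow(M))
  for (k in seq_len(ncol(M))) s <- s + tb$one_body[cbind(k, M[, k])]
  pr <- pair_index(tb$n)
  for (r in seq_len(nrow(pr))) {
    i <- pr[r, 1L]; j <- pr[r, 2L]
    s <- s + model$lambda * tb$two_body[cbind(M[, i], i, M[, j], j)]
  }
  s + model$penalty
}

# Full enumeration of the sequence space (small instances only).
enumerate_scores <- function(model, guard = 2e6) {
  n <- model$tables$n
  A <- length(model$tables$alphabet)
  m <- A^n
  if (m > guard) abort_usage(sprintf("search space %g exceeds enumeration guard", m))
  M <- codes_to_idx(seq_len(m) - 1, n, A)
  list(idx = M, score = score_idx_matrix(model, M))
}

#' Exhaustive global minimization (oracle solver)
#'
#' Enumerates every sequence; ties are broken lexicographically by alphabet
#' order (the first minimum in lexicographic enumeration wins).  Guarded to
#' `|alphabet|^n <= 1e7`.
#'
#' @param model `potts_model`.
#' @return `solve_result`.
#' @export
solve_exhaustive <- function(model) {
  n <- model$tables$n
  A <- length(model$tables$alphabet)
  m <- A^n
  if (m > 1e7) abort_usage("search space exceeds exhaustive-solver guard (1e7)")
  best_score <- Inf
  best_idx <- NULL
  chunk <- 2e5
  for (start in seq(0, m - 1, by = chunk)) {
    codes <- start:min(start + chunk - 1, m - 1)
    M <- codes_to_idx(codes, n, A)
    sc <- score_idx_matrix(model, M)
    w <- which.min(sc)
    if (sc[w] < best_score) {   # strict: keeps the lexicographically first tie
      best_score <- sc[w]
      best_idx <- M[w, ]
    }
  }
  solve_result(idx_to_seq(best_idx, model$tables$alphabet), best_score,
               method = "exhaustive")
}

#' Simulated-annealing schedule
#'
#' Geometric cooling from `t_start` to `t_end` (score units) over `n_steps`
#' temperature steps with `moves_per_step` Metropolis proposals each.  When
#' `t_start` is `NULL` the solver sets it to 10 times the standard deviation
#' of 1000 random-sequence scores of the model being solved.
#'
#' @param t_start starting temperature (score units) or `NULL` for automatic.
#' @param t_end final temperature (> 0).
#' @param n_steps number of temperature steps.
#' @param moves_per_step proposals per temperature step.
#' @param seed mandatory integer seed.
#' @return object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t_start = NULL, t_end = 0.01, n_steps = 5e4,
                            moves_per_step = 1, seed) {
  if (missing(seed)) abort_usage("anneal_schedule requires an explicit seed")
  if (!is.null(t_start) && t_start <= t_end) abort_usage("need t_start > t_end")
  if (t_end <= 0) abort_usage("need t_end > 0")
  structure(list(t_start = t_start, t_end = t_end, n_steps = as.integer(n_steps),
                 moves_per_step = as.integer(moves_per_step), seed = as.integer(seed)),
            class = "anneal_schedule")
}

#' Simulated annealing in the feasible (one-hot) space
#'
#' Metropolis walk whose moves change one residue's amino acid, so every
#' visited state is a valid sequence.  Returns the best sequence seen.
#' Deterministic for a given schedule seed.
#'
#' @param model `potts_model`.
#' @param schedule `anneal_schedule`.
#' @param init optional starting sequence (default: random from the seed).
#' @return `solve_result`.
#' @export
solve_simulated_annealing <- function(model, schedule, init = NULL) {
  if (!inherits(schedule, "anneal_schedule")) abort_usage("schedule must be an anneal_schedule")
  tb <- model$tables
  n <- tb$n
  A <- length(tb$alphabet)
  with_seed(schedule$seed, {
    t_start <- schedule$t_start
    if (is.null(t_start)) {
      sc <- vapply(seq_len(1000), function(k)
        potts_score_idx(model, sample.int(A, n, replace = TRUE)), 0)
      t_start <- max(10 * stats::sd(sc), 10 * schedule$t_end)
    }
    cur <- if (is.null(init)) sample.int(A, n, replace = TRUE)
           else seq_to_idx(init, tb$alphabet)
    F <- score_field(model, cur)
    cur_score <- potts_score_idx(model, cur)
    best <- cur; best_score <- cur_score
    total <- schedule$n_steps * schedule$moves_per_step
    pos <- sample.int(n, total, replace = TRUE)
    prop <- sample.int(A, total, replace = TRUE)
    u <- stats::runif(total)
    ratio <- (schedule$t_end / t_start)^(1 / max(1, schedule$n_steps - 1))
    temps <- rep(t_start * ratio^(seq_len(schedule$n_steps) - 1),
                 each = schedule$moves_per_step)
    for (k in seq_len(total)) {
      i <- pos[k]; b <- prop[k]; a <- cur[i]
      if (b == a) next
      delta <- F[b, i] - F[a, i]
      if (delta <= 0 || u[k] < exp(-delta / temps[k])) {
        cur[i] <- b
        cur_score <- cur_score + delta
        F <- score_field_update(F, model, cur, i, a, b)
        if (cur_score < best_score - 1e-12) {
          best <- cur; best_score <- cur_score
        }
      }
    }
    seqv <- idx_to_seq(best, tb$alphabet)
    solve_result(seqv, potts_score_idx(model, best), method = "sa",
                 seed = schedule$seed,
                 metadata = list(t_start = t_start, t_end = schedule$t_end,
                                 n_steps = schedule$n_steps,
                                 moves_per_step = schedule$moves_per_step))
  })
}

# Exhaustively optimize the residues in `block` with all others frozen.
optimize_block <- function(model, cur, block) {
  tb <- model$tables
  A <- length(tb$alphabet)
  k <- length(block)
  if (A^k > 1e6) abort_usage("block too large for exhaustive sub-solve")
  other <- setdiff(seq_len(tb$n), block)
  f <- lapply(block, function(i) {
    v <- tb$one_body[i, ]
    for (j in other) v <- v + model$lambda * tb$two_body[, i, cur[j], j]
    v
  })
  G <- codes_to_idx(seq_len(A^k) - 1, k, A)
  s <- numeric(nrow(G))
  for (c in seq_len(k)) s <- s + f[[c]][G[, c]]
  if (k > 1L) {
    pr <- pair_index(k)
    for (r in seq_len(nrow(pr))) {
      c1 <- pr[r, 1L]; c2 <- pr[r, 2L]
      s <- s + model$lambda *
        tb$two_body[cbind(G[, c1], block[c1], G[, c2], block[c2])]
    }
  }
  w <- which.min(s)
  list(letters = G[w, ], gain = s[w] - s[sum((cur[block] - 1) * A^(rev(seq_len(k)) - 1)) + 1])
}

#' Decomposition refiner (large-neighborhood descent)
#'
#' Mirrors the structure of hybrid decomposition solvers: repeatedly selects
#' small residue subsets, solves each subproblem exactly with the remaining
#' residues frozen, and accepts only improvements, so the score trace is
#' monotone non-increasing.  Deterministic block sweeps (all contiguous
#' windows, then all pairs for `block_size = 2`) are followed by seeded
#' random subsets each round.
#'
#' @param model `potts_model`.
#' @param block_size residues per subproblem (`k = n` degenerates to
#'   [solve_exhaustive()]).
#' @param rounds maximum sweeps; stops early when a sweep yields no gain.
#' @param init starting sequence (default: random from `seed`).
#' @param seed integer seed for the random subsets (and `init` if absent).
#' @return `solve_result` with the score trace in `metadata$trace`.
#' @export
solve_hybrid <- function(model, block_size = 2, rounds = 10, init = NULL, seed = 1L) {
  tb <- model$tables
  n <- tb$n
  A <- length(tb$alphabet)
  if (block_size < 1 || block_size > n) abort_usage("block_size must be in 1..n")
  if (block_size == n) return(solve_exhaustive(model))
  with_seed(seed, {
    cur <- if (is.null(init)) sample.int(A, n, replace = TRUE)
           else seq_to_idx(init, tb$alphabet)
    cur_score <- potts_score_idx(model, cur)
    trace <- cur_score
    blocks_det <- lapply(seq_len(n - block_size + 1), function(s) s:(s + block_size - 1))
    if (block_size == 2L) {
      pr <- pair_index(n)
      blocks_det <- c(blocks_det, lapply(seq_len(nrow(pr)), function(r) pr[r, ]))
    }
    for (round in seq_len(rounds)) {
      improved <- FALSE
      blocks <- c(blocks_det,
                  lapply(seq_len(n), function(...) sort(sample.int(n, block_size))))
      for (b in blocks) {
        opt <- optimize_block(model, cur, b)
        if (opt$gain < -1e-12) {
          cur[b] <- opt$letters
          cur_score <- potts_score_idx(model, cur)
          trace <- c(trace, cur_score)
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    solve_result(idx_to_seq(cur, tb$alphabet), cur_score, method = "hybrid",
                 seed = seed,
                 metadata = list(block_size = block_size, trace = trace))
  })
}

#' One-hot QUBO encoding of a Potts model
#'
#' Maps each (residue, amino acid) pair to a binary variable
#' `v = (i-1) * |alphabet| + alpha` and adds, per residue, the quadratic
#' penalty `A_w * (sum_alpha s_i_alpha - 1)^2` so that every feasible
#' (one-hot) bitstring reproduces the Potts score exactly and every
#' infeasible bitstring is pushed above the feasible optimum.  The default
#' constraint weight `A_w = 2 * (sum_i max_a |E_ia| + lambda * sum_{i<j}
#' max_ab |E_iajb|) + 1` strictly dominates any energetic gain from a
#' violation.
#'
#' @param model `potts_model`.
#' @param constraint_weight optional override of the automatic weight.
#' @return object of class `qubo_matrix` with fields `linear` (length
#'   `n * |alphabet|`), `quadratic` (upper-triangular dense matrix),
#'   `constant`, `constraint_weight` and `var_index`.
#' @export
encode_one_hot_qubo <- function(model, constraint_weight = NULL) {
  tb <- model$tables
  n <- tb$n
  A <- length(tb$alphabet)
  nv <- n * A
  pr <- pair_index(n)
  if (is.null(constraint_weight)) {
    m1 <- sum(apply(abs(tb$one_body), 1L, max))
    m2 <- 0
    for (r in seq_len(nrow(pr)))
      m2 <- m2 + max(abs(tb$two_body[, pr[r, 1L], , pr[r, 2L]]))
    constraint_weight <- 2 * (m1 + model$lambda * m2) + 1
  }
  if (constraint_weight <= 0) abort_usage("constraint weight must be positive")
  vid <- function(i, a) (i - 1L) * A + a
  linear <- as.vector(t(tb$one_body)) - constraint_weight
  Q <- matrix(0, nv, nv)
  for (i in seq_len(n)) {
    va <- vid(i, seq_len(A))
    ut <- which(upper.tri(matrix(0, A, A)), arr.ind = TRUE)
    Q[cbind(va[ut[, 1L]], va[ut[, 2L]])] <- 2 * constraint_weight
  }
  for (r in seq_len(nrow(pr))) {
    i <- pr[r, 1L]; j <- pr[r, 2L]
    Q[vid(i, seq_len(A)), vid(j, seq_len(A))] <-
      model$lambda * tb$two_body[, i, , j]
  }
  structure(list(n = n, alphabet = tb$alphabet, linear = linear, quadratic = Q,
                 constant = n * constraint_weight + model$penalty,
                 constraint_weight = constraint_weight,
                 var_index = function(i, a) (i - 1L) * A + a),
            class = "qubo_matrix")
}

#' QUBO energy of a bitstring
#'
#' @param qubo `qubo_matrix`.
#' @param bits 0/1 vector of length `n * |alphabet|`, or an assignment
#'   matrix from [assignment_from_sequence()].
#' @return energy including the constant offset.
#' @export
qubo_energy <- function(qubo, bits) {
  if (is.matrix(bits)) bits <- as.vector(t(bits))
  if (length(bits) != length(qubo$linear)) abort_usage("bitstring length mismatch")
  sum(qubo$linear * bits) + as.numeric(bits %*% qubo$quadratic %*% bits) + qubo$constant
}

#' Hyperparameter scan over (lambda, penalty) grid
#'
#' Solves one model per distinct grid cell and reports the per-cell best
#' result plus the deduplicated set of optimal sequences, mirroring the use
#' of several weightings per conformation to harvest multiple designs.
#'
#' @param tables `energy_tables`.
#' @param lambdas,penalties numeric vectors (non-empty).
#' @param solver one of `"sa+hybrid"`, `"sa"`, `"hybrid"`, `"exhaustive"`.
#' @param seed integer seed; each cell derives its own child seed.
#' @param n_steps annealing steps per cell.
#' @return list with `results` (list of `solve_result`) and `sequences`
#'   (data.frame of distinct sequences with their provenance).
#' @export
hyperparameter_scan <- function(tables, lambdas, penalties,
                                solver = c("sa+hybrid", "sa", "hybrid", "exhaustive"),
                                seed = 1L, n_steps = 2e4) {
  solver <- match.arg(solver)
  if (length(lambdas) == 0L || length(penalties) == 0L)
    abort_usage("lambda/penalty grid must be non-empty")
  grid <- unique(expand.grid(lambda = lambdas, penalty = penalties))
  results <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    model <- potts_model(tables, lambda = grid$lambda[g], penalty = grid$penalty[g])
    s <- child_seed(seed, g)
    res <- switch(solver,
      exhaustive = solve_exhaustive(model),
      sa = solve_simulated_annealing(model, anneal_schedule(n_steps = n_steps, seed = s)),
      hybrid = solve_hybrid(model, seed = s),
      `sa+hybrid` = {
        sa <- solve_simulated_annealing(model, anneal_schedule(n_steps = n_steps, seed = s))
        solve_hybrid(model, init = sa$sequence, seed = child_seed(s, 1))
      })
    res$metadata$lambda <- grid$lambda[g]
    res$metadata$penalty <- grid$penalty[g]
    results[[g]] <- res
  }
  keys <- vapply(results, function(r) seq_key(r$sequence), "")
  first <- !duplicated(keys)
  sequences <- data.frame(sequence = keys[first],
                          score = vapply(results[first], function(r) r$score, 0),
                          lambda = vapply(results[first], function(r) r$metadata$lambda, 0),
                          penalty = vapply(results[first], function(r) r$metadata$penalty, 0),
                          stringsAsFactors = FALSE)
  list(results = results, sequences = sequences)
}

#' Write solver results as JSON lines (and optionally FASTA)
#'
#' @param results list of `solve_result`.
#' @param path JSONL output path.
#' @param fasta optional FASTA output path.
#' @param conformation_id recorded per line.
#' @return `path`, invisibly.
#' @export
write_solve_results <- function(results, path, fasta = NULL, conformation_id = NA) {
  lines <- vapply(results, function(r) {
    as.character(jsonlite::toJSON(list(
      sequence = seq_key(r$sequence), score = r$score, method = r$method,
      seed = r$seed, lambda = r$metadata$lambda %||% NA,
      penalty = r$metadata$penalty %||% NA,
      conformation_id = conformation_id), auto_unbox = TRUE, digits = NA))
  }, "")
  writeLines(lines, path)
  if (!is.null(fasta)) {
    ali <- do.call(rbind, lapply(results, function(r) r$sequence))
    ids <- vapply(seq_along(results), function(k)
      sprintf("design_%d|%s|score=%.6g", k, results[[k]]$method, results[[k]]$score), "")
    bio3d::write.fasta(ids = ids, seqs = ali, file = fasta)
  }
  invisible(path)
}
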