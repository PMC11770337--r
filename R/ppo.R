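# Proximal policy optimization over the Potts landscape.
#
# The policy network embeds each residue's amino acid, feeds the embedded
# sequence through a gated recurrent unit, and maps the final hidden state
# through a softmax layer to a distribution over (position, amino-acid)
# substitution actions; a linear value head shares the recurrent trunk.
# All gradients are computed by hand (backpropagation through time) and
# verified against numerical differentiation in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' PPO training configuration
#'
#' @param d_emb embedding dimension.
#' @param d_h GRU hidden size.
#' @param clip_epsilon PPO clipping parameter (in (0, 1)).
#' @param kl_limit approximate-KL threshold above which an update epoch is
#'   rolled back.
#' @param learning_rate Adam step size.
#' @param horizon actions per episode.
#' @param episodes_per_update rollouts collected per policy update.
#' @param updates number of policy updates.
#' @param epochs gradient epochs per update.
#' @param discount,gae_lambda advantage-estimation parameters.
#' @param ent_coef,vf_coef entropy bonus and value-loss weights.
#' @param seed mandatory integer seed.
#' @return list of class `ppo_config`.
#' @export
ppo_config <- function(d_emb = 16, d_h = 64, clip_epsilon = 0.2, kl_limit = 0.1,
                       learning_rate = 3e-4, horizon = 50,
                       episodes_per_update = 4, updates = 30, epochs = 2,
                       discount = 0.99, gae_lambda = 0.95,
                       ent_coef = 0.01, vf_coef = 0.5, seed) {
  if (missing(seed)) abort_usage("ppo_config requires an explicit seed")
  if (clip_epsilon <= 0 || clip_epsilon >= 1) abort_usage("clip_epsilon must be in (0,1)")
  if (horizon < 1) abort_usage("horizon must be >= 1")
  structure(as.list(environment()), class = "ppo_config")
}

#' Initialize policy parameters
#'
#' @param n peptide length.
#' @param alphabet design alphabet.
#' @param d_emb,d_h network dimensions.
#' @param seed integer seed.
#' @return list of class `policy_params` (embedding, GRU gates, softmax
#'   output head over `n * |alphabet|` actions, value head).
#' @export
init_policy_params <- function(n, alphabet = default_alphabet(),
                               d_emb = 16, d_h = 64, seed) {
  A <- length(alphabet)
  with_seed(seed, {
    g <- function(nr, nc, sc) matrix(stats::rnorm(nr * nc, sd = sc), nr, nc)
    structure(list(
      n = n, alphabet = alphabet, d_emb = d_emb, d_h = d_h,
      E = g(A, d_emb, 0.1),
      Wz = g(d_h, d_emb, 1 / sqrt(d_emb)), Uz = g(d_h, d_h, 1 / sqrt(d_h)), bz = numeric(d_h),
      Wr = g(d_h, d_emb, 1 / sqrt(d_emb)), Ur = g(d_h, d_h, 1 / sqrt(d_h)), br = numeric(d_h),
      Wh = g(d_h, d_emb, 1 / sqrt(d_emb)), Uh = g(d_h, d_h, 1 / sqrt(d_h)), bh = numeric(d_h),
      Wout = g(n * A, d_h, 0.01), bout = numeric(n * A),
      wv = numeric(d_h), bv = 0),
      class = "policy_params")
  })
}

# Forward pass; returns distribution, value and the cache for backprop.
policy_forward <- function(params, idx) {
  n <- length(idx)
  d_h <- params$d_h
  h <- numeric(d_h)
  cache <- vector("list", n)
  for (t in seq_len(n)) {
    x <- params$E[idx[t], ]
    z <- sigmoid(params$Wz %*% x + params$Uz %*% h + params$bz)[, 1L]
    r <- sigmoid(params$Wr %*% x + params$Ur %*% h + params$br)[, 1L]
    hh <- tanh(params$Wh %*% x + params$Uh %*% (r * h) + params$bh)[, 1L]
    hn <- (1 - z) * h + z * hh
    cache[[t]] <- list(x = x, h_prev = h, z = z, r = r, hh = hh, letter = idx[t])
    h <- hn
  }
  logits <- (params$Wout %*% h + params$bout)[, 1L]
  logits <- logits - max(logits)
  p <- exp(logits)
  p <- p / sum(p)
  v <- sum(params$wv * h) + params$bv
  list(probs = p, logits = logits, v = v, h = h, cache = cache)
}

#' Action distribution of the policy at a state
#'
#' @param params `policy_params`.
#' @param state sequence (string or character vector).
#' @return probability vector over the `n * |alphabet|` actions, action
#'   index `(position - 1) * |alphabet| + amino_acid`.
#' @export
policy_distribution <- function(params, state) {
  idx <- seq_to_idx(state, params$alphabet)
  if (length(idx) != params$n) abort_usage("state length != policy n")
  policy_forward(params, idx)$probs
}

#' Apply a substitution action to a sequence
#'
#' @param state sequence.
#' @param position 1-based residue position.
#' @param amino_acid letter to place there.
#' @param alphabet design alphabet.
#' @return updated sequence (unchanged if the letter already occupies the
#'   position).
#' @export
apply_action <- function(state, position, amino_acid, alphabet = default_alphabet()) {
  res <- as_residues(state, alphabet)
  if (position < 1 || position > length(res)) abort_usage("action position out of range")
  res[position] <- as_residues(amino_acid, alphabet)
  res
}

# Score change of a single-position substitution (O(n)).
score_delta <- function(model, idx, pos, b) {
  tb <- model$tables
  a <- idx[pos]
  if (a == b) return(0)
  d <- tb$one_body[pos, b] - tb$one_body[pos, a]
  for (j in seq_len(tb$n)) if (j != pos)
    d <- d + model$lambda * (tb$two_body[idx[j], j, b, pos] - tb$two_body[idx[j], j, a, pos])
  d
}

#' Step reward on the Potts landscape
#'
#' The reward of moving from `s_t` to `s_t1` is the score *decrease*
#' `score(s_t) - score(s_t1)`, so the agent is rewarded for moving toward
#' lower scores (higher predicted affinity); identity actions earn 0, and
#' episode rewards telescope to `score(s_0) - score(s_T)`.
#'
#' @param model `potts_model`.
#' @param s_t,s_t1 sequences before and after the action.
#' @return reward in score units.
#' @export
step_reward <- function(model, s_t, s_t1) {
  potts_score(model, s_t) - potts_score(model, s_t1)
}

# Backpropagate dL/dlogits and dL/dv through the network; returns the
# gradient list (same shapes as the parameters).
policy_backward <- function(params, fw, dlogits, dv) {
  A <- nrow(params$E)
  gr <- list(E = matrix(0, A, params$d_emb),
             Wz = params$Wz * 0, Uz = params$Uz * 0, bz = numeric(params$d_h),
             Wr = params$Wr * 0, Ur = params$Ur * 0, br = numeric(params$d_h),
             Wh = params$Wh * 0, Uh = params$Uh * 0, bh = numeric(params$d_h),
             Wout = params$Wout * 0, bout = numeric(length(params$bout)),
             wv = numeric(params$d_h), bv = 0)
  gr$Wout <- outer(dlogits, fw$h)
  gr$bout <- dlogits
  gr$wv <- dv * fw$h
  gr$bv <- dv
  g <- as.vector(crossprod(params$Wout, dlogits)) + dv * params$wv
  for (t in rev(seq_along(fw$cache))) {
    c <- fw$cache[[t]]
    dz <- g * (c$hh - c$h_prev)
    dhh <- g * c$z
    dh_prev <- g * (1 - c$z)
    da_h <- dhh * (1 - c$hh^2)
    rh <- c$r * c$h_prev
    gr$Wh <- gr$Wh + outer(da_h, c$x)
    gr$Uh <- gr$Uh + outer(da_h, rh)
    gr$bh <- gr$bh + da_h
    drh <- as.vector(crossprod(params$Uh, da_h))
    dr <- drh * c$h_prev
    dh_prev <- dh_prev + drh * c$r
    da_z <- dz * c$z * (1 - c$z)
    gr$Wz <- gr$Wz + outer(da_z, c$x)
    gr$Uz <- gr$Uz + outer(da_z, c$h_prev)
    gr$bz <- gr$bz + da_z
    dh_prev <- dh_prev + as.vector(crossprod(params$Uz, da_z))
    da_r <- dr * c$r * (1 - c$r)
    gr$Wr <- gr$Wr + outer(da_r, c$x)
    gr$Ur <- gr$Ur + outer(da_r, c$h_prev)
    gr$br <- gr$br + da_r
    dh_prev <- dh_prev + as.vector(crossprod(params$Ur, da_r))
    dx <- as.vector(crossprod(params$Wz, da_z)) +
      as.vector(crossprod(params$Wr, da_r)) +
      as.vector(crossprod(params$Wh, da_h))
    gr$E[c$letter, ] <- gr$E[c$letter, ] + dx
    g <- dh_prev
  }
  gr
}

ppo_param_names <- function() c("E", "Wz", "Uz", "bz", "Wr", "Ur", "br",
                                "Wh", "Uh", "bh", "Wout", "bout", "wv", "bv")

adam_init <- function(params) {
  st <- list(t = 0)
  for (nm in ppo_param_names()) {
    st[[paste0("m_", nm)]] <- params[[nm]] * 0
    st[[paste0("v_", nm)]] <- params[[nm]] * 0
  }
  st
}

adam_step <- function(params, grad, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in ppo_param_names()) {
    m <- beta1 * st[[paste0("m_", nm)]] + (1 - beta1) * grad[[nm]]
    v <- beta2 * st[[paste0("v_", nm)]] + (1 - beta2) * grad[[nm]]^2
    st[[paste0("m_", nm)]] <- m
    st[[paste0("v_", nm)]] <- v
    mh <- m / (1 - beta1^st$t)
    vh <- v / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = st)
}

# Potts-landscape environment: states are alphabet-index vectors.
potts_env <- function(model, seed_idx) {
  list(
    reset = function() seed_idx,
    step = function(idx, action) {
      A <- length(model$tables$alphabet)
      pos <- (action - 1L) %/% A + 1L
      b <- (action - 1L) %% A + 1L
      d <- score_delta(model, idx, pos, b)
      idx[pos] <- b
      list(state = idx, reward = -d)
    })
}

# Core PPO loop over a generic environment (used directly by tests with
# synthetic bandit environments).
ppo_train_env <- function(env, n, A, config) {
  params <- init_policy_params(n, alphabet = rep("x", A), d_emb = config$d_emb,
                               d_h = config$d_h, seed = child_seed(config$seed, 1))
  params$alphabet <- NULL  # environment states are plain index vectors here
  opt <- adam_init(params)
  log_rows <- list()
  with_seed(child_seed(config$seed, 2), {
    for (up in seq_len(config$updates)) {
      states <- list(); actions <- integer(0); old_logp <- numeric(0)
      values <- numeric(0); rewards <- numeric(0); adv <- numeric(0); ret <- numeric(0)
      for (ep in seq_len(config$episodes_per_update)) {
        s <- env$reset()
        ep_v <- numeric(config$horizon + 1)
        ep_r <- numeric(config$horizon)
        ep_states <- vector("list", config$horizon)
        ep_act <- integer(config$horizon)
        ep_lp <- numeric(config$horizon)
        for (t in seq_len(config$horizon)) {
          fw <- policy_forward(params, s)
          a <- sample.int(length(fw$probs), 1L, prob = fw$probs)
          st <- env$step(s, a)
          ep_states[[t]] <- s
          ep_act[t] <- a
          ep_lp[t] <- log(fw$probs[a])
          ep_v[t] <- fw$v
          ep_r[t] <- st$reward
          s <- st$state
        }
        ep_v[config$horizon + 1] <- policy_forward(params, s)$v
        g <- 0
        ep_adv <- numeric(config$horizon)
        for (t in rev(seq_len(config$horizon))) {
          delta <- ep_r[t] + config$discount * ep_v[t + 1] - ep_v[t]
          g <- delta + config$discount * config$gae_lambda * g
          ep_adv[t] <- g
        }
        states <- c(states, ep_states)
        actions <- c(actions, ep_act)
        old_logp <- c(old_logp, ep_lp)
        values <- c(values, ep_v[seq_len(config$horizon)])
        rewards <- c(rewards, ep_r)
        adv <- c(adv, ep_adv)
        ret <- c(ret, ep_adv + ep_v[seq_len(config$horizon)])
      }
      if (stats::sd(adv) > 0) adv <- (adv - mean(adv)) / stats::sd(adv)
      m <- length(actions)
      kl <- NA_real_
      loss <- NA_real_
      skipped <- FALSE
      for (epoch in seq_len(config$epochs)) {
        acc <- NULL
        tot_loss <- 0
        for (k in seq_len(m)) {
          fw <- policy_forward(params, states[[k]])
          p <- fw$probs
          a <- actions[k]
          logp <- log(p[a])
          rho <- exp(logp - old_logp[k])
          clipped <- pmin(pmax(rho, 1 - config$clip_epsilon), 1 + config$clip_epsilon)
          use_unclipped <- (rho * adv[k]) <= (clipped * adv[k]) + 1e-12
          ent <- -sum(p * log(pmax(p, 1e-12)))
          ea <- numeric(length(p)); ea[a] <- 1
          dlogits <- numeric(length(p))
          if (use_unclipped) dlogits <- -adv[k] * rho * (ea - p)
          dlogits <- dlogits + config$ent_coef * p * (log(pmax(p, 1e-12)) + ent)
          dv <- 2 * config$vf_coef * (fw$v - ret[k])
          gr <- policy_backward(params, fw, dlogits, dv)
          tot_loss <- tot_loss - min(rho * adv[k], clipped * adv[k]) +
            config$vf_coef * (fw$v - ret[k])^2 - config$ent_coef * ent
          if (is.null(acc)) acc <- gr
          else for (nm in ppo_param_names()) acc[[nm]] <- acc[[nm]] + gr[[nm]]
        }
        for (nm in ppo_param_names()) acc[[nm]] <- acc[[nm]] / m
        loss <- tot_loss / m
        if (!is.finite(loss))
          abort_numeric(sprintf("PPO loss non-finite at update %d", up))
        prev <- params; prev_opt <- opt
        stepped <- adam_step(params, acc, opt, config$learning_rate)
        params <- stepped$params; opt <- stepped$state
        newlp <- vapply(seq_len(m), function(k)
          log(policy_forward(params, states[[k]])$probs[actions[k]]), 0)
        kl <- mean(old_logp - newlp)
        if (is.finite(config$kl_limit) && kl > config$kl_limit) {
          params <- prev; opt <- prev_opt
          skipped <- TRUE
          break
        }
      }
      log_rows[[up]] <- data.frame(update = up, mean_reward = mean(rewards),
                                   approx_kl = kl, loss = loss, skipped = skipped)
    }
  })
  list(params = params, log = do.call(rbind, log_rows))
}

#' Train a PPO policy on a Potts landscape
#'
#' Episodes start from `seed_sequence` (typically the solver optimum) and
#' roll `horizon` substitution actions; updates use the clipped surrogate
#' objective with GAE advantages from the value head, an entropy bonus, and
#' an approximate-KL guard that rolls back epochs that move the policy too
#' far.  Deterministic for a given config seed.
#'
#' @param model `potts_model`.
#' @param seed_sequence starting sequence.
#' @param config `ppo_config`.
#' @return object of class `ppo_policy`: `params`, `log` (one row per
#'   update), `config`, `seed_sequence`.
#' @export
ppo_train <- function(model, seed_sequence, config) {
  if (!inherits(config, "ppo_config")) abort_usage("config must be a ppo_config")
  alphabet <- model$tables$alphabet
  seed_idx <- seq_to_idx(seed_sequence, alphabet)
  if (length(seed_idx) != model$tables$n) abort_usage("seed sequence length mismatch")
  env <- potts_env(model, seed_idx)
  out <- ppo_train_env(env, model$tables$n, length(alphabet), config)
  out$params$alphabet <- alphabet
  out$params$n <- model$tables$n
  class(out$params) <- "policy_params"
  structure(list(params = out$params, log = out$log, config = config,
                 seed_sequence = idx_to_seq(seed_idx, alphabet)),
            class = "ppo_policy")
}

#' Harvest alternate near-optimal sequences with a trained policy
#'
#' Rolls the (stochastic) trained policy from the seed sequence and keeps
#' every distinct visited sequence whose score lies within `window` score
#' units of `best_score`; the seed itself is excluded.
#'
#' @param policy `ppo_policy` (or bare `policy_params` with matching model).
#' @param model `potts_model`.
#' @param seed_sequence rollout start (defaults to the policy's training
#'   seed sequence).
#' @param best_score reference score (default: score of `seed_sequence`).
#' @param window score window (default 5).
#' @param budget maximum environment steps.
#' @param horizon rollout length before resetting to the seed.
#' @param seed integer seed for action sampling.
#' @return object of class `alternate_set` with `members` (list of
#'   `list(sequence, score)`), `best_score`, `window`, `seed_sequence`,
#'   `steps_used`.
#' @export
collect_alternates <- function(policy, model, seed_sequence = NULL,
                               best_score = NULL, window = 5, budget = 1e4,
                               horizon = 50, seed = 1L) {
  params <- if (inherits(policy, "ppo_policy")) policy$params else policy
  alphabet <- model$tables$alphabet
  if (is.null(seed_sequence))
    seed_sequence <- if (inherits(policy, "ppo_policy")) policy$seed_sequence
                     else abort_usage("seed_sequence required")
  seed_idx <- seq_to_idx(seed_sequence, alphabet)
  if (is.null(best_score)) best_score <- potts_score_idx(model, seed_idx)
  seedkey <- seq_key(idx_to_seq(seed_idx, alphabet))
  found <- new.env(parent = emptyenv())
  A <- length(alphabet)
  env <- potts_env(model, seed_idx)
  with_seed(seed, {
    steps <- 0L
    s <- seed_idx
    score <- potts_score_idx(model, s)
    t_in_ep <- 0L
    while (steps < budget) {
      if (t_in_ep >= horizon) {
        s <- seed_idx
        score <- potts_score_idx(model, s)
        t_in_ep <- 0L
      }
      fw <- policy_forward(params, s)
      a <- sample.int(length(fw$probs), 1L, prob = fw$probs)
      st <- env$step(s, a)
      score <- score - st$reward
      s <- st$state
      steps <- steps + 1L
      t_in_ep <- t_in_ep + 1L
      if (score <= best_score + window + 1e-9) {
        key <- seq_key(idx_to_seq(s, alphabet))
        if (key != seedkey && !exists(key, envir = found, inherits = FALSE))
          assign(key, score, envir = found)
      }
    }
    members <- lapply(sort(ls(found)), function(k)
      list(sequence = strsplit(k, "")[[1]], score = get(k, envir = found)))
    structure(list(seed_sequence = idx_to_seq(seed_idx, alphabet),
                   best_score = best_score, window = window,
                   members = members, steps_used = steps),
              class = "alternate_set")
  })
}

#' @export
print.alternate_set <- function(x, ...) {
  cat(sprintf("alternate_set: %d members within %.3g of best %.6g\n",
              length(x$members), x$window, x$best_score))
  invisible(x)
}
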