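#' Configuration for the blending agent
#'
#' Defaults are the tuned values: discount 0.9193, Polyak coefficient
#' 0.0139, actor learning rate 2.26e-5, critic learning rate 5.01e-4,
#' hidden width 128, target-update frequency 2, 30 epochs.  The
#' Ornstein-Uhlenbeck exploration parameters, reward weights, replay
#' capacity and batch size are free parameters with documented defaults.
#'
#' @param gamma discount factor in (0, 1).
#' @param polyak Polyak averaging coefficient in (0, 1).
#' @param actor_lr,critic_lr Adam learning rates of the two networks.
#' @param hidden hidden width of both networks.
#' @param update_freq target networks are Polyak-updated every this many
#'   gradient steps.
#' @param epochs passes over the training states.
#' @param ou_theta,ou_mu,ou_sigma,ou_dt Ornstein-Uhlenbeck noise parameters.
#' @param w_bce,w_dr,w_balance reward weights for the negative
#'   cross-entropy, doubly-robust and balance terms; `w_dr` is automatically
#'   zeroed when no ground-truth effect is supplied (outside simulations).
#' @param buffer_capacity replay buffer capacity.
#' @param batch_size replay minibatch size.
#' @param overlap_eta positivity bound for the state's overlap indicator.
#' @param seed integer RNG seed.
#' @return an object of class `agent_config`.
#' @export
agent_config <- function(gamma = 0.9193, polyak = 0.0139,
                         actor_lr = 2.26e-5, critic_lr = 5.01e-4,
                         hidden = 128, update_freq = 2, epochs = 30,
                         ou_theta = 0.15, ou_mu = 0, ou_sigma = 0.2,
                         ou_dt = 1,
                         w_bce = 1, w_dr = 1, w_balance = 0.1,
                         buffer_capacity = 10000, batch_size = 128,
                         overlap_eta = 0.05, seed = 1L) {
  assert_that(gamma > 0 && gamma < 1, "`gamma` must be in (0, 1)")
  assert_that(polyak > 0 && polyak < 1, "`polyak` must be in (0, 1)")
  structure(list(gamma = gamma, polyak = polyak, actor_lr = actor_lr,
                 critic_lr = critic_lr, hidden = as.integer(hidden),
                 update_freq = as.integer(update_freq),
                 epochs = as.integer(epochs),
                 ou_theta = ou_theta, ou_mu = ou_mu, ou_sigma = ou_sigma,
                 ou_dt = ou_dt, w_bce = w_bce, w_dr = w_dr,
                 w_balance = w_balance,
                 buffer_capacity = as.integer(buffer_capacity),
                 batch_size = as.integer(batch_size),
                 overlap_eta = overlap_eta, seed = as.integer(seed)),
            class = "agent_config")
}

#' Build the 7-component ensemble state
#'
#' Components, in order: the two branch predictions (factual-arm outcome
#' probabilities), their uncertainties, the estimated propensity, the
#' overlap indicator (1 iff `eta <= e <= 1 - eta`), and the covariate
#' balance score.
#'
#' @param titan_out,dr_out factual-arm probabilities from the two branches.
#' @param u_titan,u_dr nonnegative prediction uncertainties.
#' @param propensity estimated propensity of the factual treatment = 1 arm.
#' @param balance_score covariate balance score (scalar or per-unit).
#' @param eta positivity bound for the overlap indicator.
#' @return a matrix with 7 columns (one row per unit).
#' @export
build_state <- function(titan_out, dr_out, u_titan, u_dr, propensity,
                        balance_score, eta = 0.05) {
  n <- length(titan_out)
  s <- cbind(titan = titan_out, dr = dr_out,
             u_titan = u_titan, u_dr = u_dr,
             propensity = propensity,
             overlap = as.numeric(propensity >= eta & propensity <= 1 - eta),
             balance = rep_len(balance_score, n))
  assert_that(all(is.finite(s)), "state components must all be finite")
  assert_that(all(u_titan >= 0) && all(u_dr >= 0),
              "uncertainties must be nonnegative")
  s
}

#' Convex blend of the two branch outputs
#'
#' `yhat = alpha * y_titan + (1 - alpha) * y_dr`, elementwise (applied per
#' arm by the pipeline).  `alpha` outside `[0, 1]` is clipped with a
#' warning.
#'
#' @param alpha blend weight(s) in `[0, 1]`.
#' @param y_titan,y_dr the two branch outputs.
#' @return blended values, always between the two inputs.
#' @export
blend <- function(alpha, y_titan, y_dr) {
  if (any(alpha < 0 | alpha > 1)) {
    warn("`alpha` outside [0, 1]: clipping")
    alpha <- clip(alpha, 0, 1)
  }
  alpha * y_titan + (1 - alpha) * y_dr
}

#' Causal-aware reward
#'
#' `r = w_bce * (-BCE(yhat, y)) + w_dr * r_DR + w_balance * r_balance`.
#' The doubly robust term `r_DR = -(pseudo - tau_true)^2` measures the
#' squared error of the unit's DR pseudo-outcome against the ground-truth
#' effect and is only available in simulation mode (its weight is zeroed
#' when `tau_true` is NULL).  The balance term is the negative sum of
#' squared weighted covariate mean differences across arms.
#'
#' @param y_hat blended factual probability in (0, 1).
#' @param y observed binary outcome.
#' @param dr_pseudo per-unit DR pseudo-outcome (or NULL).
#' @param tau_true ground-truth effect (or NULL outside simulations).
#' @param balance_penalty nonnegative scalar `sum_k ||diff_k||^2`.
#' @param weights list/vector with `w_bce`, `w_dr`, `w_balance`.
#' @return numeric reward vector.
#' @export
reward <- function(y_hat, y, dr_pseudo = NULL, tau_true = NULL,
                   balance_penalty = 0,
                   weights = c(w_bce = 1, w_dr = 1, w_balance = 0.1)) {
  w <- as.list(weights)
  r <- w$w_bce * (-bce(y_hat, y))
  if (!is.null(tau_true) && !is.null(dr_pseudo)) {
    r <- r + w$w_dr * (-(dr_pseudo - tau_true)^2)
  }
  r + w$w_balance * (-balance_penalty)
}

#' Covariate balance score
#'
#' Sum of squared inverse-propensity-weighted standardized mean differences
#' of the covariates across the two arms; zero when the weighted means
#' agree.
#'
#' @param x covariate matrix.
#' @param t binary treatment.
#' @param e propensity of treatment 1 (clipped upstream).
#' @return a nonnegative scalar.
#' @export
balance_score <- function(x, t, e) {
  x <- as.matrix(x)
  w1 <- ifelse(t == 1, 1 / e, 0)
  w0 <- ifelse(t == 0, 1 / (1 - e), 0)
  m1 <- colSums(x * w1) / sum(w1)
  m0 <- colSums(x * w0) / sum(w0)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  sum(((m1 - m0) / s)^2)
}

#' One Ornstein-Uhlenbeck step
#'
#' `N' = N + theta (mu - N) dt + sigma sqrt(dt) eps`, `eps ~ N(0, 1)`:
#' mean-reverting Gaussian exploration noise.
#'
#' @param noise current noise value.
#' @param theta reversion speed (>= 0).
#' @param mu long-run mean.
#' @param sigma volatility (>= 0).
#' @param dt time step (> 0).
#' @return next noise value.
#' @export
ou_step <- function(noise, theta = 0.15, mu = 0, sigma = 0.2, dt = 1) {
  assert_that(theta >= 0 && sigma >= 0 && dt > 0, "invalid OU parameters")
  noise + theta * (mu - noise) * dt + sigma * sqrt(dt) * rnorm(length(noise))
}

#' Polyak (soft) target update
#'
#' `target <- tau * current + (1 - tau) * target`, elementwise over every
#' parameter array.
#'
#' @param current,target parameter lists/arrays with identical shapes.
#' @param tau averaging coefficient in `[0, 1]`.
#' @return the updated target parameters.
#' @export
polyak_update <- function(current, target, tau) {
  assert_that(tau >= 0 && tau <= 1, "`tau` must be in [0, 1]")
  if (is.list(current)) {
    return(purrr::map2(current, target, polyak_update, tau = tau))
  }
  assert_that(length(current) == length(target), "shape mismatch")
  tau * current + (1 - tau) * target
}

# ---- tiny two-layer MLPs with manual gradients --------------------------

mlp_init <- function(n_in, hidden) {
  list(W1 = matrix(rnorm(n_in * hidden, 0, sqrt(2 / (n_in + hidden))),
                   n_in, hidden),
       b1 = numeric(hidden),
       w2 = rnorm(hidden, 0, sqrt(1 / hidden)),
       b2 = 0)
}

mlp_forward <- function(par, x) {
  h_pre <- sweep(x %*% par$W1, 2, par$b1, "+")
  h <- tanh(h_pre)
  out <- as.numeric(h %*% par$w2 + par$b2)
  list(out = out, h = h, h_pre = h_pre)
}

# gradients of sum(d_out * out) wrt parameters and inputs
mlp_backward <- function(par, x, fwd, d_out) {
  dh <- outer(d_out, par$w2) * (1 - fwd$h^2)
  list(grads = list(W1 = t(x) %*% dh, b1 = colSums(dh),
                    w2 = colSums(fwd$h * d_out), b2 = sum(d_out)),
       d_x = dh %*% t(par$W1))
}

actor_forward <- function(par, s) {
  f <- mlp_forward(par, s)
  list(alpha = sigmoid(f$out), fwd = f)
}

#' Train the blending agent
#'
#' Deterministic actor-critic (DDPG-style) on one-step episodes: each unit
#' is an episode whose successor state is the next sampled unit (the
#' contextual-bandit reading of the MDP, with the discount retained).
#' Transitions go to a uniform replay buffer; OU noise drives exploration;
#' target networks are Polyak-updated every `update_freq` steps.  The reward
#' is recomputed for the action actually taken.
#'
#' @param states state matrix from [build_state()].
#' @param labels observed binary outcomes aligned with the states.
#' @param reward_context list with per-unit vectors `titan1`, `titan0`,
#'   `dr1`, `dr0` (per-arm branch probabilities), `t_fact` (factual arm),
#'   and optionally `dr_pseudo`, `tau_true`, `balance_penalty`.  When
#'   `tau_true` is present (simulation mode) the causal reward term is the
#'   negative squared error of the *blended* effect implied by the action,
#'   so causal validity — not factual accuracy alone — steers the learned
#'   blend.
#' @param config an [agent_config()].
#' @return an object of class `rl_agent` with actor/critic (+ targets) and
#'   an `alpha_trace` tibble of the per-epoch mean training blend weight.
#' @export
train_agent <- function(states, labels, reward_context,
                        config = agent_config()) {
  s <- as.matrix(states)
  n <- nrow(s)
  assert_that(length(labels) == n, "states/labels length mismatch")
  set.seed(config$seed)
  actor <- mlp_init(ncol(s), config$hidden)
  critic <- mlp_init(ncol(s) + 1L, config$hidden)
  actor_t <- actor
  critic_t <- critic
  opt_a <- adam_init(actor)
  opt_c <- adam_init(critic)
  rc <- reward_context
  w <- c(w_bce = config$w_bce,
         w_dr = if (is.null(rc$tau_true)) 0 else config$w_dr,
         w_balance = config$w_balance)
  buf_s <- matrix(NA_real_, config$buffer_capacity, ncol(s))
  buf_a <- numeric(config$buffer_capacity)
  buf_r <- numeric(config$buffer_capacity)
  buf_s2 <- matrix(NA_real_, config$buffer_capacity, ncol(s))
  buf_n <- 0L
  buf_pos <- 0L
  step <- 0L
  noise <- 0
  trace <- list()
  blend_arm <- function(alpha, i) {
    y1 <- blend(alpha, rc$titan1[i], rc$dr1[i])
    y0 <- blend(alpha, rc$titan0[i], rc$dr0[i])
    ifelse(rc$t_fact[i] == 1, y1, y0)
  }
  # per-unit reward for an action; the stored reward is centered at the
  # fixed equal-weight blend (a baseline independent of the action), a
  # standard policy-gradient variance reduction that leaves the optimal
  # policy unchanged but removes the large unit-level reward noise
  unit_reward <- function(a, i) {
    y_hat <- clip(blend_arm(a, i), 1e-6, 1 - 1e-6)
    tau_blend <- if (is.null(rc$tau_true)) NULL else {
      blend(a, rc$titan1[i] - rc$titan0[i], rc$dr1[i] - rc$dr0[i])
    }
    reward(y_hat, labels[i],
           dr_pseudo = tau_blend, tau_true = rc$tau_true[i],
           balance_penalty = rc$balance_penalty %||% 0,
           weights = w)
  }
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    alphas_ep <- numeric(n)
    for (pos in seq_len(n)) {
      i <- ord[pos]
      i_next <- ord[if (pos == n) 1L else pos + 1L]
      af <- actor_forward(actor, s[i, , drop = FALSE])
      noise <- ou_step(noise, config$ou_theta, config$ou_mu,
                       config$ou_sigma, config$ou_dt)
      a <- clip(af$alpha + noise, 0, 1)
      alphas_ep[pos] <- a
      r <- unit_reward(a, i) - unit_reward(0.5, i)
      buf_pos <- (buf_pos %% config$buffer_capacity) + 1L
      buf_s[buf_pos, ] <- s[i, ]
      buf_a[buf_pos] <- a
      buf_r[buf_pos] <- r
      buf_s2[buf_pos, ] <- s[i_next, ]
      buf_n <- min(buf_n + 1L, config$buffer_capacity)
      if (buf_n < config$batch_size) next
      step <- step + 1L
      idx <- sample.int(buf_n, config$batch_size, replace = TRUE)
      sb <- buf_s[idx, , drop = FALSE]
      ab <- buf_a[idx]
      rb <- buf_r[idx]
      sb2 <- buf_s2[idx, , drop = FALSE]
      # critic update: TD target with target networks
      a2 <- actor_forward(actor_t, sb2)$alpha
      q2 <- mlp_forward(critic_t, cbind(sb2, a2))$out
      target <- rb + config$gamma * q2
      cf <- mlp_forward(critic, cbind(sb, ab))
      d_q <- 2 * (cf$out - target) / config$batch_size
      cb <- mlp_backward(critic, cbind(sb, ab), cf, d_q)
      stc <- adam_step(critic, cb$grads, opt_c, config$critic_lr)
      critic <- stc$params; opt_c <- stc$state
      # actor update: ascend Q(s, pi(s))
      afb <- actor_forward(actor, sb)
      qf <- mlp_forward(critic, cbind(sb, afb$alpha))
      cb2 <- mlp_backward(critic, cbind(sb, afb$alpha), qf,
                          rep(-1 / config$batch_size, config$batch_size))
      d_alpha <- cb2$d_x[, ncol(sb) + 1L]
      d_pre <- d_alpha * afb$alpha * (1 - afb$alpha)
      ab2 <- mlp_backward(actor, sb, afb$fwd, d_pre)
      sta <- adam_step(actor, ab2$grads, opt_a, config$actor_lr)
      actor <- sta$params; opt_a <- sta$state
      if (step %% config$update_freq == 0L) {
        actor_t <- polyak_update(actor, actor_t, config$polyak)
        critic_t <- polyak_update(critic, critic_t, config$polyak)
      }
    }
    trace[[epoch]] <- tibble::tibble(epoch = epoch,
                                     mean_alpha = mean(alphas_ep))
  }
  structure(list(actor = actor, critic = critic, actor_target = actor_t,
                 critic_target = critic_t, config = config,
                 alpha_trace = dplyr::bind_rows(trace),
                 buffer_count = buf_n),
            class = "rl_agent")
}

#' @export
print.rl_agent <- function(x, ...) {
  la <- utils::tail(x$alpha_trace$mean_alpha, 1)
  cat("rl_agent: hidden", x$config$hidden, "| epochs trained",
      nrow(x$alpha_trace), "| final mean alpha",
      format(la, digits = 3), "\n")
  invisible(x)
}

#' Blended predictions from a fitted agent
#'
#' Inference is noise-free: the deterministic actor maps each state to its
#' blend weight `alpha` (clipped to `[0, 1]`), and the per-arm branch
#' probabilities are combined as a convex blend; the blended effect is the
#' difference of the blended arm probabilities.
#'
#' @param agent a fitted `rl_agent`.
#' @param states state matrix.
#' @param titan_preds,dr_preds two-column matrices (or lists with `p1`,
#'   `p0`) of per-arm probabilities from each branch.
#' @return a tibble with `alpha`, `p1`, `p0`, `ite`.
#' @export
predict_ensemble <- function(agent, states, titan_preds, dr_preds) {
  pick <- function(x, arm) {
    if (is.list(x) && !is.data.frame(x)) x[[arm]]
    else as.matrix(x)[, arm]
  }
  alpha <- clip(actor_forward(agent$actor, as.matrix(states))$alpha, 0, 1)
  p1 <- blend(alpha, pick(titan_preds, "p1"), pick(dr_preds, "p1"))
  p0 <- blend(alpha, pick(titan_preds, "p0"), pick(dr_preds, "p0"))
  tibble::tibble(alpha = alpha, p1 = p1, p0 = p0, ite = p1 - p0)
}
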