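#' Weights and parameters of the four-term unsupervised cost
#'
#' The cost is the sum of a phase-progression penalty (PP), a distribution
#' term (D), a singularity penalty (S) and a marginal-singularity penalty
#' (M). `a` and `b` bound the penalty-free band of per-window phase
#' progression: with a 150 Hz stream and a gait cycle of roughly 100-200
#' samples, the natural progression of consecutive windows is about
#' 2 pi / cycle-length radians, which the default band (-2.3 deg, 4 deg\]
#' admits while forbidding stalls, jumps and sustained backward motion.
#' `c` marks the progression penalized hardest. `alpha`, `gamma` and `lam`
#' weight D, S and M; `sigma` is the width of the Gaussian bump that S and
#' M apply to the pre-phase magnitude, and `sigma_w` the standard deviation
#' of the input noise used by M (both in standardized units).
#'
#' @param pp_weight weight of the phase-progression penalty.
#' @param a,b,c penalty-profile breakpoints in radians; must satisfy
#'   -pi < c < a < 0 < b < pi so the profile's branches partition
#'   (-pi, pi\].
#' @param alpha distribution-term weight.
#' @param gamma singularity-term weight.
#' @param lam marginal-singularity-term weight.
#' @param sigma Gaussian width of the singularity terms.
#' @param sigma_w input-noise standard deviation of the marginal term.
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(pp_weight = 1,
                         a = -2.3 * pi / 180,
                         b = 4 * pi / 180,
                         c = -135 * pi / 180,
                         alpha = 0.45,
                         gamma = 0.55,
                         lam = 0.55,
                         sigma = 1.0,
                         sigma_w = 0.1) {
  if (!(-pi < c && c < a && a < 0 && 0 < b && b < pi)) {
    stop("penalty breakpoints must satisfy -pi < c < a < 0 < b < pi",
         call. = FALSE)
  }
  if (alpha <= 0 || gamma <= 0 || lam <= 0 || sigma <= 0 || sigma_w <= 0) {
    stop("alpha, gamma, lam, sigma and sigma_w must be positive",
         call. = FALSE)
  }
  structure(
    list(pp_weight = pp_weight, a = a, b = b, c = c, alpha = alpha,
         gamma = gamma, lam = lam, sigma = sigma, sigma_w = sigma_w),
    class = "loss_weights"
  )
}

#' Phase-progression penalty profile
#'
#' Piecewise-cosine bump over the progression angle `nu`: identically 0 on
#' the permitted band (a, b\], rising smoothly on either side, reaching its
#' maximum 1 at `nu = c`, and continuous across the +/-pi wrap.
#'
#' @param nu progression angle(s) in radians, each in (-pi, pi\].
#' @param weights a [loss_weights()].
#' @return penalty value(s) in \[0, 1\].
#' @export
penalty_profile <- function(nu, weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  if (any(nu <= -pi | nu > pi)) {
    stop("nu must lie in (-pi, pi]", call. = FALSE)
  }
  a <- weights$a; b <- weights$b; c <- weights$c
  out <- numeric(length(nu))
  i1 <- nu <= c
  i2 <- nu > c & nu <= a
  i4 <- nu > b
  out[i1] <- cos((pi / 2) * (nu[i1] - c) / (2 * pi + c - b))
  out[i2] <- cos((pi / 2) * (nu[i2] - c) / (a - c))
  out[i4] <- cos((pi / 2) * (nu[i4] - c - 2 * pi) / (2 * pi + c - b))
  out
}

# dP/dnu, branch by branch (0 on the permitted band).
.penalty_profile_grad <- function(nu, weights) {
  a <- weights$a; b <- weights$b; c <- weights$c
  k_out <- (pi / 2) / (2 * pi + c - b)
  k_in <- (pi / 2) / (a - c)
  out <- numeric(length(nu))
  i1 <- nu <= c
  i2 <- nu > c & nu <= a
  i4 <- nu > b
  out[i1] <- -k_out * sin((pi / 2) * (nu[i1] - c) / (2 * pi + c - b))
  out[i2] <- -k_in * sin((pi / 2) * (nu[i2] - c) / (a - c))
  out[i4] <- -k_out * sin((pi / 2) * (nu[i4] - c - 2 * pi) / (2 * pi + c - b))
  out
}

#' Signed phase progression between two unit vectors
#'
#' The angle by which the current phase vector has advanced past the
#' previous one: `atan2` of their cross and dot products, in (-pi, pi\].
#' Positive values are anticlockwise progression.
#'
#' @param previous,current numeric unit 2-vectors (norm within 1e-6 of 1).
#' @return progression angle in radians.
#' @export
phase_progression <- function(previous, current) {
  stopifnot(length(previous) == 2L, length(current) == 2L)
  if (abs(sum(previous^2) - 1) > 2e-6 || abs(sum(current^2) - 1) > 2e-6) {
    stop("phase_progression expects unit vectors", call. = FALSE)
  }
  wrap_angle(atan2(previous[1] * current[2] - current[1] * previous[2],
                   previous[1] * current[1] + previous[2] * current[2]))
}

# Gaussian bump applied to the pre-phase magnitude by the S and M terms.
.gauss_bump <- function(r2, sigma) {
  exp(-r2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
}

# Loss components (and optionally dL/dV for each stream) from the raw
# pre-phase outputs. Vp, Vc, Vn: n x 2 matrices for the previous, current
# and noise-perturbed current windows. Exposed internally so the component
# laws can be unit-tested on constructed outputs, with `guard` switchable.
.loss_terms <- function(Vp, Vc, Vn, weights, grad = FALSE, guard = TRUE) {
  n <- nrow(Vc)
  sig <- weights$sigma
  r2p <- rowSums(Vp^2); r2c <- rowSums(Vc^2); r2n <- rowSums(Vn^2)
  if (guard && any(c(r2p, r2c) < 1e-24)) {
    bad <- which(pmin(r2p, r2c) < 1e-24)[1]
    stop("singularity: pre-phase vector at the origin for pair ", bad,
         call. = FALSE)
  }
  rp <- sqrt(pmax(r2p, 1e-300)); rc <- sqrt(pmax(r2c, 1e-300))
  Up <- Vp / rp; Uc <- Vc / rc
  cross <- Up[, 1] * Uc[, 2] - Uc[, 1] * Up[, 2]
  dot <- Up[, 1] * Uc[, 1] + Up[, 2] * Uc[, 2]
  nu <- wrap_angle(atan2(cross, dot))

  pp <- mean(penalty_profile(nu, weights))
  mx <- mean(Uc[, 1]); my <- mean(Uc[, 2])
  d <- weights$alpha * (mx^2 + my^2)
  gs <- .gauss_bump(r2c, sig)
  gn <- .gauss_bump(r2n, sig)
  s <- weights$gamma * mean(gs)
  m <- weights$lam * mean(gn)
  total <- weights$pp_weight * pp + d + s + m
  out <- list(pp = pp, d = d, s = s, m = m, total = total, n_pairs = n)
  if (!grad) return(out)

  # dL/dnu from PP; dnu/dV via the atan2-angle gradient of each stream.
  dnu <- (weights$pp_weight / n) * .penalty_profile_grad(nu, weights)
  rot <- function(V) cbind(-V[, 2], V[, 1])
  dVc <- rot(Vc) * (dnu / r2c)
  dVp <- -rot(Vp) * (dnu / r2p)
  # D: through the Euclidean normalization of the current stream.
  cd <- 2 * weights$alpha / n
  proj <- mx * Uc[, 1] + my * Uc[, 2]
  dVc <- dVc + cd * (cbind(mx - proj * Uc[, 1], my - proj * Uc[, 2]) / rc)
  # S and M: Gaussian bump of |V|.
  dVc <- dVc - (weights$gamma / (n * sig^2)) * gs * Vc
  dVn <- -(weights$lam / (n * sig^2)) * gn * Vn
  c(out, list(dVp = dVp, dVc = dVc, dVn = dVn))
}

# Backpropagate dL/dV through the network; fwd is a .forward(...,
# keep_activations = TRUE) result for input X. Returns per-layer gradients.
.backprop <- function(params, X, fwd, G) {
  grads <- vector("list", 6L)
  A_prev <- fwd$acts[[5]]
  grads[[6]] <- list(W = crossprod(A_prev, G), b = colSums(G))
  G <- G %*% t(params[[6]]$W)                      # into identity layer 5
  grads[[5]] <- list(W = crossprod(fwd$acts[[4]], G), b = colSums(G))
  for (l in 4:1) {
    G <- (G %*% t(params[[l + 1]]$W)) * (1 - fwd$acts[[l]]^2)
    A_in <- if (l == 1L) X else fwd$acts[[l - 1L]]
    grads[[l]] <- list(W = crossprod(A_in, G), b = colSums(G))
  }
  grads
}

# Total loss and parameter gradient for one batch of pairs (plus the
# noise-perturbed current windows). Three forward/backward passes share the
# same weights.
.loss_and_grad <- function(params, prev, curr, noisy, weights) {
  fp <- .forward(params, prev, keep_activations = TRUE)
  fc <- .forward(params, curr, keep_activations = TRUE)
  fn <- .forward(params, noisy, keep_activations = TRUE)
  lt <- .loss_terms(fp$V, fc$V, fn$V, weights, grad = TRUE)
  gp <- .backprop(params, prev, fp, lt$dVp)
  gc <- .backprop(params, curr, fc, lt$dVc)
  gn <- .backprop(params, noisy, fn, lt$dVn)
  grads <- lapply(1:6, function(l) list(
    W = gp[[l]]$W + gc[[l]]$W + gn[[l]]$W,
    b = gp[[l]]$b + gc[[l]]$b + gn[[l]]$b
  ))
  list(loss = lt, grads = grads)
}

#' Evaluate the four-term cost on a batch of window pairs
#'
#' Runs the network on the previous and current windows of every pair and on
#' noise-perturbed copies of the current windows, then evaluates the
#' phase-progression penalty (mean penalty profile of the pairwise
#' progressions), the distribution term (squared distance of the mean unit
#' vector from the circle centre, weighted by alpha), and the singularity /
#' marginal-singularity terms (Gaussian bump of the pre-phase magnitude,
#' weighted by gamma and lambda).
#'
#' @param params a `phase_network`.
#' @param pairs a [build_window_pairs()] / [bind_window_pairs()] result.
#' @param weights a [loss_weights()].
#' @param noise_seed integer seed for the marginal term's input noise.
#' @return object of class `loss_breakdown`: list with components `pp`,
#'   `d`, `s`, `m`, their weighted sum `total`, and `n_pairs`.
#' @export
loss_breakdown <- function(params, pairs, weights = loss_weights(),
                           noise_seed = 1L) {
  stopifnot(inherits(params, "phase_network"), inherits(pairs, "window_pairs"),
            inherits(weights, "loss_weights"))
  n <- nrow(pairs$curr)
  if (n == 0L) stop("empty batch of window pairs", call. = FALSE)
  noisy <- withr::with_seed(as.integer(noise_seed),
    pairs$curr + matrix(stats::rnorm(n * 28L, 0, weights$sigma_w), n, 28L))
  lt <- .loss_terms(.forward(params, pairs$prev), .forward(params, pairs$curr),
                    .forward(params, noisy), weights)
  structure(lt, class = "loss_breakdown")
}

#' Training configuration for the phase network
#'
#' @param iterations number of gradient steps.
#' @param learning_rate Adam step size.
#' @param batch_size pairs per iteration; `NULL` uses the full batch every
#'   step.
#' @param batch_strategy how minibatches are drawn when `batch_size` is
#'   set. `"segment"` (default) picks one source trajectory and a
#'   contiguous run of its pairs: the distribution term then measures phase
#'   density uniformity within a single walk, which is what actually pins
#'   the phase to a uniform advance — pooled over several subjects with
#'   different cadences, per-subject density lumps can cancel and the term
#'   loses its grip. `"random"` samples pairs independently across the
#'   whole pool.
#' @param augment_sd optional input-noise augmentation: standard deviation
#'   of zero-mean Gaussian noise added to the training inputs (all 28
#'   dimensions of both windows of each pair) before every forward pass,
#'   fresh each iteration, in standardized units. Off (0) by default —
#'   at the levels tried it slows convergence of the progression terms
#'   more than it regularizes.
#' @param adam_epsilon Adam denominator constant. The default 1e-3 is
#'   deliberately large: with a tiny epsilon, Adam amplifies the
#'   exponentially small but consistently outward gradients of the
#'   singularity terms into a steady drift that inflates the pre-phase
#'   magnitude and freezes the phase angles (whose sensitivity falls off as
#'   1 / magnitude).
#' @param seed integer seed governing initialization order of the noise
#'   stream and minibatch sampling.
#' @return object of class `train_config`.
#' @export
train_config <- function(iterations = 10000L, learning_rate = 1e-3,
                         batch_size = NULL,
                         batch_strategy = c("segment", "random"),
                         adam_epsilon = 1e-3,
                         augment_sd = 0,
                         seed = 1L) {
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 1L) {
    stop("iterations must be >= 1", call. = FALSE)
  }
  if (augment_sd < 0) stop("augment_sd must be >= 0", call. = FALSE)
  structure(
    list(iterations = iterations, learning_rate = learning_rate,
         optimizer = "adam", batch_size = batch_size,
         batch_strategy = match.arg(batch_strategy),
         adam_epsilon = adam_epsilon, augment_sd = augment_sd,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Train the phase network by unsupervised gradient descent
#'
#' Minimizes the four-term cost with Adam, drawing fresh input noise for the
#' marginal-singularity term at every iteration (and, when `batch_size` is
#' set, a fresh minibatch of pairs). Gradients are computed by analytic
#' backpropagation through the shared network; the run is fully reproducible
#' from the config seed.
#'
#' @param pairs training batch from [build_window_pairs()] or
#'   [bind_window_pairs()].
#' @param config a [train_config()].
#' @param weights a [loss_weights()].
#' @param params optional starting `phase_network`; defaults to
#'   [init_params()] with the config seed.
#' @param progress print the loss every `progress` iterations (0 = silent).
#' @return list with the trained `params` and `history`, a data.frame with
#'   one row per iteration (`iteration`, `pp`, `d`, `s`, `m`, `total`).
#' @export
train_phase_model <- function(pairs, config = train_config(),
                              weights = loss_weights(), params = NULL,
                              progress = 0L) {
  stopifnot(inherits(pairs, "window_pairs"), inherits(config, "train_config"),
            inherits(weights, "loss_weights"))
  n <- nrow(pairs$curr)
  if (n < 1L) stop("need at least one window pair to train", call. = FALSE)
  if (is.null(params)) params <- init_params(config$seed)
  bs <- config$batch_size
  if (!is.null(bs)) bs <- min(as.integer(bs), n)

  mW <- lapply(params, function(l) list(W = 0 * l$W, b = 0 * l$b))
  vW <- mW
  b1 <- 0.9; b2 <- 0.999; lr <- config$learning_rate
  eps <- if (is.null(config$adam_epsilon)) 1e-3 else config$adam_epsilon
  hist <- matrix(NA_real_, config$iterations, 5L)
  colnames(hist) <- c("pp", "d", "s", "m", "total")

  segment <- !is.null(bs) && identical(config$batch_strategy, "segment")
  groups <- if (is.null(pairs$group)) rep(1L, n) else pairs$group
  group_idx <- split(seq_len(n), groups)

  withr::with_seed(config$seed + 1L, {
    for (it in seq_len(config$iterations)) {
      idx <- if (is.null(bs)) {
        seq_len(n)
      } else if (segment) {
        # one contiguous run of pairs from one source trajectory
        gi <- group_idx[[sample.int(length(group_idx), 1L)]]
        if (length(gi) <= bs) gi else {
          s <- sample.int(length(gi) - bs + 1L, 1L)
          gi[s:(s + bs - 1L)]
        }
      } else {
        sample.int(n, bs)
      }
      prev <- pairs$prev[idx, , drop = FALSE]
      curr <- pairs$curr[idx, , drop = FALSE]
      if (config$augment_sd > 0) {
        prev <- prev + matrix(stats::rnorm(length(prev), 0, config$augment_sd),
                              nrow(prev), 28L)
        curr <- curr + matrix(stats::rnorm(length(curr), 0, config$augment_sd),
                              nrow(curr), 28L)
      }
      noisy <- curr + matrix(stats::rnorm(length(curr), 0, weights$sigma_w),
                             nrow(curr), 28L)
      lg <- .loss_and_grad(params, prev, curr, noisy, weights)
      lt <- lg$loss
      if (!is.finite(lt$total)) {
        comp <- c(pp = lt$pp, d = lt$d, s = lt$s, m = lt$m)
        stop("non-finite loss at iteration ", it, " (component: ",
             paste(names(comp)[!is.finite(comp)], collapse = ", "), ")",
             call. = FALSE)
      }
      hist[it, ] <- c(lt$pp, lt$d, lt$s, lt$m, lt$total)
      c1 <- 1 - b1^it; c2 <- 1 - b2^it
      for (l in 1:6) {
        for (p in c("W", "b")) {
          g <- lg$grads[[l]][[p]]
          mW[[l]][[p]] <- b1 * mW[[l]][[p]] + (1 - b1) * g
          vW[[l]][[p]] <- b2 * vW[[l]][[p]] + (1 - b2) * g^2
          params[[l]][[p]] <- params[[l]][[p]] -
            lr * (mW[[l]][[p]] / c1) / (sqrt(vW[[l]][[p]] / c2) + eps)
        }
      }
      if (progress > 0L && it %% progress == 0L) {
        message(sprintf("iter %6d  total %.5f  pp %.5f  d %.5f  s %.5f  m %.5f",
                        it, lt$total, lt$pp, lt$d, lt$s, lt$m))
      }
    }
  })
  history <- data.frame(iteration = seq_len(config$iterations), hist)
  list(params = params, history = history)
}

# Flatten parameters to a vector and back; used by the finite-difference
# gradient check.
.flatten_params <- function(params) {
  unlist(lapply(params, function(l) c(as.numeric(l$W), l$b)))
}

.unflatten_params <- function(theta, like) {
  out <- like
  pos <- 0L
  for (l in seq_along(like)) {
    nw <- length(like[[l]]$W)
    out[[l]]$W <- matrix(theta[pos + seq_len(nw)], nrow(like[[l]]$W),
                         ncol(like[[l]]$W))
    pos <- pos + nw
    nb <- length(like[[l]]$b)
    out[[l]]$b <- theta[pos + seq_len(nb)]
    pos <- pos + nb
  }
  out
}
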