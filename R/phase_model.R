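.LAYER_DIMS <- c(28L, 25L, 25L, 25L, 25L, 25L, 2L)

#' Initialize phase-network parameters
#'
#' The network has six affine layers, 28 -> 25 -> 25 -> 25 -> 25 -> 25 -> 2:
#' five fully connected hidden layers of 25 nodes (hyperbolic tangent after
#' the first four, identity after the fifth) feeding the 2-node pre-phase
#' layer, for 3377 scalar parameters in total. Weights are drawn uniformly
#' on +/- 1/sqrt(fan-in) per layer; biases start at zero.
#'
#' @param seed integer; the same seed reproduces the parameters
#'   bit-identically.
#' @return object of class `phase_network`: list of layers, each with a
#'   weight matrix `W` (in x out) and bias vector `b`.
#' @export
init_params <- function(seed = 1L) {
  dims <- .LAYER_DIMS
  layers <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(length(dims) - 1L), function(l) {
      fan_in <- dims[l]
      s <- 1 / sqrt(fan_in)
      list(W = matrix(stats::runif(fan_in * dims[l + 1L], -s, s),
                      fan_in, dims[l + 1L]),
           b = rep(0, dims[l + 1L]))
    })
  })
  structure(layers, class = "phase_network")
}

#' Number of scalar parameters of a phase network
#' @param params a `phase_network`.
#' @return integer count.
#' @export
n_params <- function(params) {
  stopifnot(inherits(params, "phase_network"))
  sum(vapply(params, function(l) length(l$W) + length(l$b), 0))
}

# Batched forward pass. X: n x 28 matrix. Returns V (n x 2); with
# keep_activations the post-activation output of every hidden layer is
# retained for backpropagation.
.forward <- function(params, X, keep_activations = FALSE) {
  A <- X
  acts <- if (keep_activations) vector("list", 5L) else NULL
  for (l in 1:4) {
    A <- tanh(sweep(A %*% params[[l]]$W, 2, params[[l]]$b, `+`))
    if (keep_activations) acts[[l]] <- A
  }
  A <- sweep(A %*% params[[5]]$W, 2, params[[5]]$b, `+`)  # identity activation
  if (keep_activations) acts[[5]] <- A
  V <- sweep(A %*% params[[6]]$W, 2, params[[6]]$b, `+`)
  if (keep_activations) list(V = V, acts = acts) else V
}

#' Pre-phase output for one feature window
#'
#' Deterministic forward pass of the network on a single 28-value input
#' (7 standardized x, 7 y, 7 heading-x, 7 heading-y values), returning the
#' 2-vector from the pre-phase layer before normalization onto the unit
#' circle.
#'
#' @param params a `phase_network`.
#' @param window numeric vector of 28 finite values.
#' @return numeric 2-vector V.
#' @export
prephase <- function(params, window) {
  stopifnot(inherits(params, "phase_network"))
  if (length(window) != 28L || any(!is.finite(window))) {
    stop("malformed window: expected 28 finite values", call. = FALSE)
  }
  as.numeric(.forward(params, matrix(window, 1L, 28L)))
}

#' Normalize a pre-phase vector onto the unit circle
#'
#' Euclidean normalization of the 2-node pre-phase output; the angle of the
#' resulting unit vector is the continuous gait phase.
#'
#' @param V numeric 2-vector.
#' @return list with `unit_vector` (length-2, unit norm), `angle` (radians
#'   in (-pi, pi\]) and `prephase_magnitude` (|V|).
#' @export
to_phase <- function(V) {
  stopifnot(is.numeric(V), length(V) == 2L)
  r <- sqrt(sum(V^2))
  if (!is.finite(r) || r < 1e-12) {
    stop("singularity: pre-phase vector is at the origin", call. = FALSE)
  }
  u <- V / r
  list(unit_vector = u, angle = atan2(u[2], u[1]), prephase_magnitude = r)
}

#' Stream phases over a feature series
#'
#' Causal sliding-window inference: one phase per window end index
#' `i >= 12` (0-based), each computed from samples `<= i` only. Only the
#' current 7-sample window is fed to the network; window pairs exist solely
#' for the training loss.
#'
#' @param params a `phase_network`.
#' @param feat a [feature_series()].
#' @return data.frame with one row per emitted phase: `end_index` (0-based
#'   sample the phase is aligned to), `angle` (radians in (-pi, pi\]),
#'   unit-vector components `ux`, `uy`, and `magnitude` (pre-phase |V|).
#' @export
infer_stream <- function(params, feat) {
  stopifnot(inherits(params, "phase_network"), inherits(feat, "feature_series"))
  n <- length(feat$x)
  if (n < 13L) stop("need at least 13 samples to emit a phase", call. = FALSE)
  end_idx <- 12:(n - 1)
  V <- .forward(params, .window_matrix(feat, end_idx))
  r <- sqrt(rowSums(V^2))
  if (any(r < 1e-12)) {
    stop("singularity: pre-phase vector at the origin for window ending at ",
         "sample ", end_idx[which(r < 1e-12)[1]], call. = FALSE)
  }
  ux <- V[, 1] / r
  uy <- V[, 2] / r
  data.frame(end_index = end_idx, angle = atan2(uy, ux),
             ux = ux, uy = uy, magnitude = r)
}

#' Save / load phase-network parameters as JSON
#'
#' Portable text serialization: layer shapes plus flattened weights, with an
#' optional metadata block (seed, training configuration). The loader
#' validates the layer shapes against the fixed architecture.
#'
#' @param params a `phase_network`.
#' @param path JSON file path.
#' @param meta optional named list stored alongside the weights.
#' @return `path` (write) or the restored `phase_network` (read).
#' @export
write_phase_model <- function(params, path, meta = NULL) {
  stopifnot(inherits(params, "phase_network"))
  obj <- list(
    architecture = .LAYER_DIMS,
    layers = lapply(params, function(l)
      list(dim = dim(l$W), W = as.numeric(l$W), b = l$b)),
    meta = meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phase_model
#' @export
read_phase_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  dims <- .LAYER_DIMS
  if (!identical(as.integer(unlist(obj$architecture)), dims)) {
    stop("model file architecture does not match 28-25-25-25-25-25-2",
         call. = FALSE)
  }
  layers <- lapply(seq_len(length(dims) - 1L), function(l) {
    lay <- obj$layers[[l]]
    d <- as.integer(unlist(lay$dim))
    if (!identical(d, c(dims[l], dims[l + 1L]))) {
      stop("layer ", l, " has wrong shape in model file", call. = FALSE)
    }
    list(W = matrix(as.numeric(unlist(lay$W)), d[1], d[2]),
         b = as.numeric(unlist(lay$b)))
  })
  structure(layers, class = "phase_network")
}
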