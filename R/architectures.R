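# PQC classifier architectures: AEPQC (8-qubit amplitude-embedding circuit
# with quantum pooling), the QCNN convolutional kernels K1/K2 and the 6-qubit
# classification head, plus the simple fusion alternatives.

.KERNEL_NPARAM <- c(k1 = 8L, k2 = 39L)
.AEPQC_NPARAM <- 112L
.CHEAD_NPARAM <- 18L
.QCNN_CHANNELS <- 27L
.AEPQC_CHANNELS <- 25L
.AEPQC_INPUT_LEN <- 250L

# 8-qubit AEPQC program: three U3 layers interleaved with two ring layers of
# IsingXX entanglers, then quantum pooling on the four alternating
# neighbouring pairs (two-branch conditional U3, deferred measurement).
# 3*24 + 2*8 + 4*6 = 112 trainable angles. Readout: Z on the two
# lowest-index surviving wires (1 and 3).
.aepqc_program <- function() {
  steps <- list()
  idx <- 0L
  u3_layer <- function(wires) {
    for (w in wires) {
      steps[[length(steps) + 1L]] <<- .step("U3", w, "w", idx + 1:3)
      idx <<- idx + 3L
    }
  }
  ring <- function(n) {
    for (i in 0:(n - 1L)) {
      steps[[length(steps) + 1L]] <<-
        .step("IsingXX", c(i, (i + 1L) %% n), "w", idx + 1L)
      idx <<- idx + 1L
    }
  }
  u3_layer(0:7)
  ring(8L)
  u3_layer(0:7)
  ring(8L)
  u3_layer(0:7)
  for (m in c(0L, 2L, 4L, 6L)) {
    steps[[length(steps) + 1L]] <- .step("COND_U3", c(m, m + 1L), "w",
                                         idx + 1:6)
    idx <- idx + 6L
  }
  structure(.prog(8L, steps), n_params = idx, readout = c(1L, 3L))
}

# 4-qubit convolutional kernels. All parameters (the 4 embedding angles and
# the kernel weights) are bound per row so a whole batch of window positions
# and channels runs at once; feature columns 1:4 are the RY embedding, the
# remainder the weights.
#  K1: RY+RZ rotation per wire (8 weights) + circular CNOT; readout Z(0), Z(2).
#  K2: U3 layer / IsingXX (0,1),(2,3) / U3 layer / IsingXX (1,2) / pooling
#      0->1, 2->3 by two-branch conditional U3; 36 U3 + 3 entangling = 39
#      weights; readout Z on survivors 1 and 3.
.kernel_program <- function(kind = c("k1", "k2")) {
  kind <- match.arg(kind)
  steps <- list()
  for (w in 0:3)
    steps[[length(steps) + 1L]] <- .step("RY", w, "f", w + 1L)
  idx <- 4L
  if (kind == "k1") {
    for (w in 0:3) {
      steps[[length(steps) + 1L]] <- .step("RY", w, "f", idx + 1L)
      idx <- idx + 1L
    }
    for (w in 0:3) {
      steps[[length(steps) + 1L]] <- .step("RZ", w, "f", idx + 1L)
      idx <- idx + 1L
    }
    for (i in 0:3)
      steps[[length(steps) + 1L]] <- .step("CNOT", c(i, (i + 1L) %% 4L))
    readout <- c(0L, 2L)
  } else {
    for (w in 0:3) {
      steps[[length(steps) + 1L]] <- .step("U3", w, "f", idx + 1:3)
      idx <- idx + 3L
    }
    steps[[length(steps) + 1L]] <- .step("IsingXX", c(0L, 1L), "f", idx + 1L)
    steps[[length(steps) + 1L]] <- .step("IsingXX", c(2L, 3L), "f", idx + 2L)
    idx <- idx + 2L
    for (w in 0:3) {
      steps[[length(steps) + 1L]] <- .step("U3", w, "f", idx + 1:3)
      idx <- idx + 3L
    }
    steps[[length(steps) + 1L]] <- .step("IsingXX", c(1L, 2L), "f", idx + 1L)
    idx <- idx + 1L
    for (m in c(0L, 2L)) {
      steps[[length(steps) + 1L]] <- .step("COND_U3", c(m, m + 1L), "f",
                                           idx + 1:6)
      idx <- idx + 6L
    }
    readout <- c(1L, 3L)
  }
  structure(.prog(4L, steps), n_params = idx - 4L, readout = readout)
}

# 6-qubit classification head: amplitude embedding of the 54 channel scores
# (pad 10), RY/RZ/RX rotation layers (18 weights) and a circular CNOT ring;
# readout Z(0), Z(1).
.chead_program <- function() {
  steps <- list()
  for (w in 0:5)
    steps[[length(steps) + 1L]] <- .step("RY", w, "w", w + 1L)
  for (w in 0:5)
    steps[[length(steps) + 1L]] <- .step("RZ", w, "w", 6L + w + 1L)
  for (w in 0:5)
    steps[[length(steps) + 1L]] <- .step("RX", w, "w", 12L + w + 1L)
  for (i in 0:5)
    steps[[length(steps) + 1L]] <- .step("CNOT", c(i, (i + 1L) %% 6L))
  structure(.prog(6L, steps), n_params = 18L, readout = c(0L, 1L))
}

#' Specify a PQC classifier architecture
#'
#' Constructs the untrained model description for either architecture:
#'
#' * `"aepqc"`: an 8-qubit circuit taking the flattened 250-feature vector of
#'   a 25-channel x 10-sample window by amplitude embedding (6 padding
#'   zeros), with three U3 layers, two IsingXX entangling rings and quantum
#'   pooling on four alternating qubit pairs — 112 trainable parameters.
#' * `"qcnn"`: a per-channel quantum convolution. A 4-qubit kernel (`"k1"`:
#'   8 weights; `"k2"`: 39 weights) slides over the 10 time samples with
#'   window 4 and stride 2, across 4 layers (10 -> 8 -> 6 -> 4 -> 2), weights
#'   shared across positions but separate per channel and layer. The 27x2
#'   channel scores are fused into 2 class scores by the 6-qubit
#'   classification head (`fusion = "c_head"`, 18 weights) or by simple
#'   channel-wise reduction (`"avg"`, `"max"`, `"amax"`).
#'
#' Class scores are Pauli-Z expectations in \eqn{[-1, 1]}; softmax is applied
#' only inside the cross-entropy loss.
#'
#' @param family `"aepqc"` or `"qcnn"`.
#' @param kernel QCNN kernel, `"k1"` or `"k2"` (QCNN only).
#' @param fusion QCNN fusion mode: `"c_head"`, `"avg"`, `"max"` or `"amax"`.
#' @param n_channels Input channels: 25 for AEPQC (after pruning), 27 for
#'   QCNN.
#' @return An object of class `pqc_model`.
#' @examples
#' count_params(pqc_model("aepqc"))        # 112
#' count_params(pqc_model("qcnn", "k1"))   # 4*27*8 + 18
#' @export
pqc_model <- function(family = c("aepqc", "qcnn"),
                      kernel = c("k1", "k2"),
                      fusion = c("c_head", "avg", "max", "amax"),
                      n_channels = NULL) {
  family <- match.arg(family)
  if (family == "aepqc") {
    if (!missing(kernel) || !missing(fusion))
      stop("kernel/fusion apply only to the qcnn family")
    n_channels <- n_channels %||% .AEPQC_CHANNELS
    if (n_channels != .AEPQC_CHANNELS)
      stop("aepqc expects 25 channels (27 minus 2 pruned)")
    prog <- .aepqc_program()
    if (attr(prog, "n_params") != .AEPQC_NPARAM)
      stop(sprintf("aepqc build produced %d parameters, expected %d",
                   attr(prog, "n_params"), .AEPQC_NPARAM))
    m <- list(family = family, kernel = NULL, fusion = NULL,
              n_channels = n_channels, window_len = 10L,
              input_len = .AEPQC_INPUT_LEN, n_classes = 2L,
              n_params = .AEPQC_NPARAM)
  } else {
    kernel <- match.arg(kernel)
    fusion <- match.arg(fusion)
    n_channels <- as.integer(n_channels %||% .QCNN_CHANNELS)
    P <- .KERNEL_NPARAM[[kernel]]
    n_kernel <- 4L * n_channels * P
    n_head <- if (fusion == "c_head") .CHEAD_NPARAM else 0L
    m <- list(family = family, kernel = kernel, fusion = fusion,
              n_channels = n_channels, window_len = 10L,
              kernel_window = 4L, stride = 2L, n_layers = 4L,
              n_classes = 2L, kernel_nparam = P,
              n_params = n_kernel + n_head)
  }
  structure(m, class = "pqc_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the AEPQC model
#'
#' Convenience constructor for `pqc_model("aepqc")`; fails unless the
#' constructed circuit has exactly 112 trainable parameters.
#'
#' @return A `pqc_model`.
#' @export
build_aepqc <- function() pqc_model("aepqc")

#' @export
print.pqc_model <- function(x, ...) {
  if (x$family == "aepqc")
    cat(sprintf("<pqc_model AEPQC: 8 qubits, input %d, %d trainable parameters>\n",
                x$input_len, x$n_params))
  else
    cat(sprintf(
      "<pqc_model QCNN-%s (%s fusion): %d channels, %d trainable parameters>\n",
      toupper(x$kernel), x$fusion, x$n_channels, x$n_params))
  invisible(x)
}

#' Number of trainable parameters of a model
#'
#' @param model A [pqc_model()].
#' @return Non-negative integer count of trainable angles.
#' @export
count_params <- function(model) {
  stopifnot(inherits(model, "pqc_model"))
  model$n_params
}

#' Map flat weight positions to their role in the architecture
#'
#' Every trainable angle is addressable exactly once: the returned table has
#' one row per position of the flat weight vector, naming the component
#' (`circuit`, `kernel` or `head`), the layer, the (1-based) channel for
#' per-channel kernel weights, and the parameter index within the component.
#'
#' @param model A [pqc_model()].
#' @return A data.frame with columns `pos`, `component`, `layer`, `channel`,
#'   `param`.
#' @export
weight_index_map <- function(model) {
  stopifnot(inherits(model, "pqc_model"))
  if (model$family == "aepqc")
    return(data.frame(pos = seq_len(model$n_params), component = "circuit",
                      layer = NA_integer_, channel = NA_integer_,
                      param = seq_len(model$n_params)))
  P <- model$kernel_nparam
  C <- model$n_channels
  kern <- expand.grid(param = seq_len(P), channel = seq_len(C),
                      layer = 1:4)
  out <- data.frame(pos = seq_len(4L * C * P), component = "kernel",
                    layer = kern$layer, channel = kern$channel,
                    param = kern$param)
  if (identical(model$fusion, "c_head"))
    out <- rbind(out, data.frame(pos = nrow(out) + 1:18,
                                 component = "head", layer = NA_integer_,
                                 channel = NA_integer_, param = 1:18))
  out
}

#' Random initial weights for a model
#'
#' Independent uniform draws on \eqn{[-\pi/10, \pi/10]} per angle: small
#' initial angles keep the early circuit close to the identity.
#'
#' @param model A [pqc_model()].
#' @param seed Optional integer seed.
#' @return Numeric weight vector of length `count_params(model)`.
#' @export
init_weights <- function(model, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stats::runif(count_params(model), -pi / 10, pi / 10)
}

# ---- forward passes -------------------------------------------------------

.zero_state_rows <- function(R, dim_) {
  A <- matrix(0i, R, dim_)
  A[, 1] <- 1 + 0i
  A
}

# Batched AEPQC: X is (N x 250) of scaled features; returns scores (N x 2).
.aepqc_batch <- function(X, weights) {
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stop("cannot amplitude-embed an all-zero input row")
  A0 <- cbind(X / nrm, matrix(0, nrow(X), 6L)) + 0i
  prog <- .aepqc_program()
  fwd <- .prog_forward(prog, theta = weights, A0 = A0)
  .prog_zexp(fwd$A, 8L, attr(prog, "readout"))
}

.aepqc_batch_grad <- function(X, weights, Gs) {
  nrm <- sqrt(rowSums(X^2))
  A0 <- cbind(X / nrm, matrix(0, nrow(X), 6L)) + 0i
  prog <- .aepqc_program()
  res <- .prog_vjp(prog, theta = weights, A0 = A0,
                   readout = attr(prog, "readout"), Gbar = Gs)
  list(scores = res$values, gweights = res$gtheta)
}

#' AEPQC forward pass
#'
#' Amplitude-embeds a flattened, scaled 250-feature window on 8 qubits
#' (6 padding zeros), runs the AEPQC circuit and returns the Z expectations
#' of the two readout wires as class scores.
#'
#' @param window_flat Numeric vector of length 250 (25 channels x 10
#'   samples, channel-major, already robust-arctan scaled).
#' @param weights Numeric vector of 112 trainable angles.
#' @return Numeric class-score vector of length 2, each in `[-1, 1]`.
#' @export
aepqc_forward <- function(window_flat, weights) {
  if (length(window_flat) != .AEPQC_INPUT_LEN)
    stop(sprintf("aepqc input must have length %d, got %d",
                 .AEPQC_INPUT_LEN, length(window_flat)))
  stopifnot(length(weights) == .AEPQC_NPARAM)
  drop(.aepqc_batch(matrix(window_flat, 1), weights))
}

# Batched kernel evaluation: feats (R x 4) in [0, pi], Wrow (R x P).
.kernel_batch <- function(feats, Wrow, prog) {
  Fm <- cbind(feats, Wrow)
  fwd <- .prog_forward(prog, F = Fm, A0 = .zero_state_rows(nrow(Fm), 16L))
  .prog_zexp(fwd$A, 4L, attr(prog, "readout"))
}

.kernel_batch_vjp <- function(feats, Wrow, prog, Gbar) {
  Fm <- cbind(feats, Wrow)
  res <- .prog_vjp(prog, F = Fm, A0 = .zero_state_rows(nrow(Fm), 16L),
                   readout = attr(prog, "readout"), Gbar = Gbar)
  list(values = res$values, gfeats = res$gF[, 1:4, drop = FALSE],
       gw = res$gF[, -(1:4), drop = FALSE])
}

#' Evaluate one convolutional kernel application
#'
#' Angle-embeds 4 features (RY rotations) and runs the chosen 4-qubit kernel
#' circuit, returning its two Z-expectation outputs.
#'
#' @param features_4 Numeric length 4, values in `[0, pi]`.
#' @param kernel_weights Numeric kernel weights (8 for K1, 39 for K2).
#' @param kind `"k1"` or `"k2"`.
#' @return Numeric vector of 2 values in `[-1, 1]`.
#' @examples
#' kernel_forward(rep(0, 4), rep(0, 8), "k1")  # c(1, 1): state stays |0000>
#' @export
kernel_forward <- function(features_4, kernel_weights,
                           kind = c("k1", "k2")) {
  kind <- match.arg(kind)
  if (length(features_4) != 4L)
    stop("kernel takes exactly 4 features")
  if (any(features_4 < 0 | features_4 > pi))
    stop("kernel features must lie in [0, pi]")
  if (length(kernel_weights) != .KERNEL_NPARAM[[kind]])
    stop(sprintf("kernel %s takes %d weights, got %d", kind,
                 .KERNEL_NPARAM[[kind]], length(kernel_weights)))
  prog <- .kernel_program(kind)
  drop(.kernel_batch(matrix(features_4, 1),
                     matrix(kernel_weights, 1), prog))
}

#' Classification-head forward pass
#'
#' Amplitude-embeds the 54 channel scores on 6 qubits (10 padding zeros) and
#' applies RY/RZ/RX rotation layers (18 trainable angles) with a circular
#' CNOT ring; class scores are the Z expectations of wires 0 and 1.
#'
#' @param flat_54 Numeric vector of length 54 (27 channels x 2 scores,
#'   channel-major), not all zero.
#' @param head_weights Numeric vector of 18 angles.
#' @return Numeric class-score vector of length 2.
#' @export
c_head_forward <- function(flat_54, head_weights) {
  if (length(flat_54) != 54L)
    stop(sprintf("classification head takes 54 values, got %d",
                 length(flat_54)))
  stopifnot(length(head_weights) == .CHEAD_NPARAM)
  drop(.chead_batch(matrix(flat_54, 1), head_weights)$scores)
}

.chead_batch <- function(H, head_w) {
  if (ncol(H) > 64L) stop("classification head capacity is 64 amplitudes")
  nrm <- sqrt(rowSums(H^2))
  if (any(nrm == 0)) stop("cannot amplitude-embed an all-zero input row")
  A0 <- cbind(H / nrm, matrix(0, nrow(H), 64L - ncol(H))) + 0i
  prog <- .chead_program()
  fwd <- .prog_forward(prog, theta = head_w, A0 = A0)
  list(scores = .prog_zexp(fwd$A, 6L, attr(prog, "readout")),
       A0 = A0, nrm = nrm, prog = prog)
}

.chead_batch_grad <- function(H, head_w, Gs) {
  cb <- .chead_batch(H, head_w)
  res <- .prog_vjp(cb$prog, theta = head_w, A0 = cb$A0,
                   readout = attr(cb$prog, "readout"), Gbar = Gs)
  G <- 2 * Re(res$lambda0)
  afull <- Re(cb$A0)
  dots <- rowSums(G * afull)
  jj <- seq_len(ncol(H))
  gH <- (G[, jj, drop = FALSE] - dots * afull[, jj, drop = FALSE]) / cb$nrm
  list(scores = res$values, ghead = res$gtheta, gH = gH)
}

#' Fuse per-channel class scores
#'
#' Column-wise (per class) reduction of the channels x 2 score matrix:
#' `avg` is the mean, `max` the maximum, `amax` the value of largest absolute
#' magnitude with its sign preserved.
#'
#' @param channel_scores Numeric matrix (channels x 2), finite.
#' @param mode `"avg"`, `"max"` or `"amax"`.
#' @return Numeric class-score vector of length 2.
#' @examples
#' fuse(cbind(c(0.2, -0.9, 0.5), c(0.1, 0.2, 0.3)), "amax")
#' @export
fuse <- function(channel_scores, mode = c("avg", "max", "amax")) {
  mode <- match.arg(mode)
  channel_scores <- as.matrix(channel_scores)
  if (nrow(channel_scores) < 1L) stop("no channel scores to fuse")
  if (any(!is.finite(channel_scores))) stop("channel scores must be finite")
  apply(channel_scores, 2, switch(mode,
    avg = mean,
    max = max,
    amax = function(v) v[which.max(abs(v))]))
}

# ---- batched QCNN ---------------------------------------------------------

.qcnn_layer_sizes <- function(L0 = 10L, n_layers = 4L, window = 4L,
                              stride = 2L) {
  sizes <- integer(n_layers + 1L)
  sizes[1] <- L0
  for (l in seq_len(n_layers))
    sizes[l + 1L] <- sizes[l] - (window - stride)
  sizes
}

.qcnn_kernel_w <- function(model, weights, layer) {
  P <- model$kernel_nparam
  C <- model$n_channels
  off <- (layer - 1L) * C * P
  matrix(weights[off + seq_len(C * P)], nrow = C, byrow = TRUE)
}

# Forward over a batch: Xq is (N x C x 10) already in [0, pi]. Rows of the
# working matrix are (sample, channel) pairs with channel varying fastest.
.qcnn_batch <- function(Xq, model, weights, keep_inputs = FALSE) {
  N <- dim(Xq)[1]; C <- model$n_channels
  stopifnot(dim(Xq)[2] == C, dim(Xq)[3] == model$window_len)
  prog <- .kernel_program(model$kernel)
  R <- N * C
  cur <- matrix(aperm(Xq, c(2, 1, 3)), R, model$window_len)
  chan_row <- rep(seq_len(C), N)
  ins <- if (keep_inputs) vector("list", model$n_layers) else NULL
  for (l in seq_len(model$n_layers)) {
    if (keep_inputs) ins[[l]] <- cur
    Wrow <- .qcnn_kernel_w(model, weights, l)[chan_row, , drop = FALSE]
    Lin <- ncol(cur)
    K <- (Lin - model$kernel_window) %/% model$stride + 1L
    out <- matrix(0, R, 2L * K)
    for (k in seq_len(K)) {
      colsk <- (2L * k - 1L):(2L * k + 2L)
      out[, c(2L * k - 1L, 2L * k)] <-
        .kernel_batch(cur[, colsk, drop = FALSE], Wrow, prog)
    }
    cur <- if (l < model$n_layers) (out + 1) * pi / 2 else out
  }
  cs <- aperm(array(cur, c(C, N, 2L)), c(2, 1, 3))  # N x C x 2
  H <- t(matrix(aperm(array(cur, c(C, N, 2L)), c(3, 1, 2)), 2L * C, N))
  scores <- switch(model$fusion,
    c_head = .chead_batch(H, weights[length(weights) - 17:0])$scores,
    avg = apply(cs, c(1, 3), mean),
    max = apply(cs, c(1, 3), max),
    amax = apply(cs, c(1, 3), function(v) v[which.max(abs(v))]))
  list(scores = scores, channel_scores = cs, H = H, ins = ins,
       prog = prog, chan_row = chan_row)
}

# Full reverse pass: Gs is dLoss/dscores (N x 2); returns the flat weight
# gradient. Kernel forwards are recomputed per window position during the
# sweep (the kernel always restarts from |0000>, so only the layer inputs
# need keeping).
.qcnn_batch_grad <- function(Xq, model, weights, Gs, fwd = NULL) {
  N <- dim(Xq)[1]; C <- model$n_channels
  if (is.null(fwd)) fwd <- .qcnn_batch(Xq, model, weights, keep_inputs = TRUE)
  P <- model$kernel_nparam
  gw <- numeric(length(weights))
  R <- N * C
  if (model$fusion == "c_head") {
    hb <- .chead_batch_grad(fwd$H, weights[length(weights) - 17:0], Gs)
    gw[length(weights) - 17:0] <- hb$ghead
    Gout <- matrix(aperm(array(t(hb$gH), c(2L, C, N)), c(2, 3, 1)), R, 2L)
  } else {
    cs <- fwd$channel_scores
    Gcs <- array(0, dim(cs))
    for (j in 1:2) {
      if (model$fusion == "avg") {
        Gcs[, , j] <- Gs[, j] / C
      } else {
        pick <- apply(cs[, , j, drop = FALSE], 1,
                      if (model$fusion == "max") which.max
                      else function(v) which.max(abs(v)))
        Gcs[cbind(seq_len(N), pick, j)] <- Gs[, j]
      }
    }
    Gout <- matrix(aperm(Gcs, c(2, 1, 3)), R, 2L)
  }
  for (l in rev(seq_len(model$n_layers))) {
    cur <- fwd$ins[[l]]
    Wrow <- .qcnn_kernel_w(model, weights, l)[fwd$chan_row, , drop = FALSE]
    Lin <- ncol(cur)
    K <- (Lin - model$kernel_window) %/% model$stride + 1L
    Gin <- matrix(0, R, Lin)
    gWl <- matrix(0, C, P)
    for (k in seq_len(K)) {
      colsk <- (2L * k - 1L):(2L * k + 2L)
      vj <- .kernel_batch_vjp(cur[, colsk, drop = FALSE], Wrow, fwd$prog,
                              Gout[, c(2L * k - 1L, 2L * k), drop = FALSE])
      gWl <- gWl + rowsum(vj$gw, fwd$chan_row, reorder = TRUE)
      Gin[, colsk] <- Gin[, colsk] + vj$gfeats
    }
    off <- (l - 1L) * C * P
    gw[off + seq_len(C * P)] <- gw[off + seq_len(C * P)] + as.vector(t(gWl))
    if (l > 1L) Gout <- Gin * (pi / 2)
  }
  gw
}

#' QCNN forward pass for one trial window
#'
#' Runs the per-channel quantum convolution (4 layers, window 4, stride 2,
#' temporal length 10 -> 8 -> 6 -> 4 -> 2; kernel outputs are affinely
#' remapped from \eqn{[-1,1]} to \eqn{[0,\pi]} between layers) and fuses the
#' channels x 2 score matrix into 2 class scores.
#'
#' @param trial_window Numeric matrix (channels x 10) with values in
#'   `[0, pi]`.
#' @param weights Flat weight vector (kernel weights per layer and channel,
#'   then 18 head weights when `fusion = "c_head"`).
#' @param kernel `"k1"` or `"k2"`.
#' @param fusion Fusion mode.
#' @return List with `scores` (length 2) and `channel_scores`
#'   (channels x 2).
#' @export
qcnn_forward <- function(trial_window, weights, kernel = c("k1", "k2"),
                         fusion = c("c_head", "avg", "max", "amax")) {
  kernel <- match.arg(kernel)
  fusion <- match.arg(fusion)
  trial_window <- as.matrix(trial_window)
  model <- pqc_model("qcnn", kernel, fusion,
                     n_channels = nrow(trial_window))
  if (ncol(trial_window) != model$window_len)
    stop(sprintf("expected %d time samples per channel, got %d",
                 model$window_len, ncol(trial_window)))
  if (any(trial_window < 0 | trial_window > pi))
    stop("qcnn input values must lie in [0, pi]")
  if (length(weights) != model$n_params)
    stop(sprintf("expected %d weights, got %d", model$n_params,
                 length(weights)))
  Xq <- array(0, c(1L, nrow(trial_window), ncol(trial_window)))
  Xq[1, , ] <- trial_window
  fwd <- .qcnn_batch(Xq, model, weights)
  list(scores = drop(fwd$scores), channel_scores = fwd$channel_scores[1, , ])
}

# ---- unified model interface ---------------------------------------------

# X: (N x channels x 10) robust-arctan scaled windows. The QCNN shifts its
# input by pi/2 internally (the [0, pi] embedding range); AEPQC amplitude-
# embeds the scaled values directly.
.model_scores <- function(model, weights, X) {
  if (length(weights) != model$n_params)
    stop(sprintf("expected %d weights, got %d", model$n_params,
                 length(weights)))
  if (model$family == "aepqc") {
    if (dim(X)[2] != model$n_channels)
      stop(sprintf("aepqc expects %d channels, got %d", model$n_channels,
                   dim(X)[2]))
    Xf <- t(matrix(aperm(X, c(3, 2, 1)), model$input_len, dim(X)[1]))
    .aepqc_batch(Xf, weights)
  } else {
    .qcnn_batch(X + pi / 2, model, weights)$scores
  }
}

.softmax_ce <- function(scores, y) {
  # y: integer class index 0/1
  m <- pmax(scores[, 1], scores[, 2])
  e <- exp(scores - m)
  p <- e / rowSums(e)
  n <- nrow(scores)
  iy <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(p[iy], 1e-300)))
  hot <- matrix(0, n, 2)
  hot[iy] <- 1
  list(loss = loss, p = p, dscores = (p - hot) / n,
       acc = mean(max.col(scores, ties.method = "first") == y + 1L))
}

# Loss, accuracy and full weight gradient for one batch.
.model_loss_grad <- function(model, weights, X, y) {
  if (model$family == "aepqc") {
    Xf <- t(matrix(aperm(X, c(3, 2, 1)), model$input_len, dim(X)[1]))
    scores <- .aepqc_batch(Xf, weights)
    ce <- .softmax_ce(scores, y)
    gb <- .aepqc_batch_grad(Xf, weights, ce$dscores)
    list(loss = ce$loss, acc = ce$acc, grad = gb$gweights, scores = scores)
  } else {
    Xq <- X + pi / 2
    fwd <- .qcnn_batch(Xq, model, weights, keep_inputs = TRUE)
    ce <- .softmax_ce(fwd$scores, y)
    gw <- .qcnn_batch_grad(Xq, model, weights, ce$dscores, fwd = fwd)
    list(loss = ce$loss, acc = ce$acc, grad = gw, scores = fwd$scores)
  }
}

#' Loss and exact gradient of a model on a batch
#'
#' Cross-entropy of the softmaxed class scores together with the full
#' reverse-mode gradient with respect to every trainable weight. Exposed so
#' the gradient contract can be checked against finite differences.
#'
#' @param model A [pqc_model()].
#' @param weights Flat weight vector.
#' @param x Scaled window array (n x channels x 10).
#' @param y Integer class labels (0/1) or a factor with two levels.
#' @return List with `loss`, `acc`, `grad` (same length as `weights`) and
#'   `scores`.
#' @export
model_loss_grad <- function(model, weights, x, y) {
  y <- .as_class_index(y)
  res <- .model_loss_grad(model, weights, x, y)
  if (!is.finite(res$loss)) stop("non-finite training loss")
  res
}

.as_class_index <- function(y) {
  if (is.factor(y)) as.integer(y) - 1L
  else as.integer(y)
}

# ---- model save/load ------------------------------------------------------

#' Save a model specification and weights as plain text
#'
#' Key-value archive: spec fields round-trip bit-exactly, weights at full
#' `%.17g` precision (within 1e-15).
#'
#' @param model A [pqc_model()].
#' @param weights Flat weight vector of length `count_params(model)`.
#' @param path Output file path.
#' @export
write_pqc_model <- function(model, weights, path) {
  stopifnot(inherits(model, "pqc_model"),
            length(weights) == model$n_params)
  lines <- c(
    sprintf("family %s", model$family),
    if (!is.null(model$kernel)) sprintf("kernel %s", model$kernel),
    if (!is.null(model$fusion)) sprintf("fusion %s", model$fusion),
    sprintf("n_channels %d", model$n_channels),
    sprintf("n_params %d", model$n_params),
    paste("weights", paste(sprintf("%.17g", weights), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Load a model written by [write_pqc_model()]
#'
#' @param path File path.
#' @return List with `model` (a [pqc_model()]) and `weights`.
#' @export
read_pqc_model <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " ")
  keys <- vapply(kv, `[[`, character(1), 1)
  get1 <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) NULL else kv[[i]][-1]
  }
  family <- get1("family")
  model <- if (family == "aepqc") pqc_model("aepqc")
    else pqc_model("qcnn", get1("kernel"), get1("fusion"),
                   n_channels = as.integer(get1("n_channels")))
  weights <- as.numeric(get1("weights"))
  if (length(weights) != model$n_params)
    stop("weight count in file does not match the model specification")
  list(model = model, weights = weights)
}
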