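#' Supported parameterized gate kinds
#'
#' The simulator's gate set: the general single-qubit unitary `U3`, the Pauli
#' rotations `RY`, `RZ`, `RX`, the two-qubit entanglers `CNOT` and `IsingXX`,
#' and the measurement-conditioned `COND_U3` used by quantum pooling
#' (a two-branch controlled U3, see [pool_conditional_u3()]).
#'
#' @format A character vector of gate names.
#' @export
GATE_KINDS <- c("U3", "RY", "RZ", "RX", "CNOT", "IsingXX", "COND_U3")

.gate_arity <- c(U3 = 1L, RY = 1L, RZ = 1L, RX = 1L,
                 CNOT = 2L, IsingXX = 2L, COND_U3 = 2L)
.gate_nparam <- c(U3 = 3L, RY = 1L, RZ = 1L, RX = 1L,
                  CNOT = 0L, IsingXX = 1L, COND_U3 = 6L)

#' Describe one gate of a circuit
#'
#' A gate specification holds the gate kind, the (0-based) qubit wires it acts
#' on and its real angle parameters in radians. For two-qubit gates the first
#' wire is the more significant one in the gate's own 2-qubit basis (for
#' `CNOT` and `COND_U3` it is the control / measured wire).
#'
#' @param kind One of `GATE_KINDS`.
#' @param wires Integer vector of distinct qubit indices (0-based), length 1
#'   for single-qubit gates, 2 otherwise.
#' @param params Numeric angles in radians: 3 for `U3`, 1 for `RY`/`RZ`/`RX`/
#'   `IsingXX`, none for `CNOT`, 6 (3 per branch) for `COND_U3`.
#' @param trainable Logical flag per parameter (recycled).
#' @return An object of class `gate_spec`.
#' @examples
#' gate_spec("RY", 0, pi / 2)
#' gate_spec("CNOT", c(0, 1))
#' @export
gate_spec <- function(kind, wires, params = numeric(0), trainable = TRUE) {
  kind <- match.arg(kind, GATE_KINDS)
  wires <- as.integer(wires)
  if (anyDuplicated(wires) || any(wires < 0L))
    stop("gate wires must be distinct non-negative qubit indices")
  if (length(wires) != .gate_arity[[kind]])
    stop(sprintf("gate %s acts on %d wire(s), got %d",
                 kind, .gate_arity[[kind]], length(wires)))
  params <- as.numeric(params)
  if (length(params) != .gate_nparam[[kind]])
    stop(sprintf("gate %s takes %d parameter(s), got %d",
                 kind, .gate_nparam[[kind]], length(params)))
  if (length(params) && any(!is.finite(params)))
    stop("gate parameters must be finite")
  structure(list(kind = kind, wires = wires, params = params,
                 trainable = rep_len(as.logical(trainable),
                                     length(params))),
            class = "gate_spec")
}

#' @export
print.gate_spec <- function(x, ...) {
  cat(sprintf("<gate %s wires=(%s)%s>\n", x$kind,
              paste(x$wires, collapse = ","),
              if (length(x$params))
                paste0(" params=(", paste(signif(x$params, 4), collapse = ","), ")")
              else ""))
  invisible(x)
}

#' Unitary matrix of a gate
#'
#' Returns the closed-form 2x2 or 4x4 complex unitary of a gate
#' specification. The single-qubit unitary is
#' \deqn{U3(\theta,\phi,\delta) = \begin{pmatrix}
#'   \cos(\theta/2) & -e^{i\delta}\sin(\theta/2) \\
#'   e^{i\phi}\sin(\theta/2) & e^{i(\delta+\phi)}\cos(\theta/2)
#' \end{pmatrix}}
#' with `RY`, `RZ`, `RX` the usual Pauli rotations and `IsingXX`
#' \eqn{\exp(-i \phi X\otimes X / 2)}. `COND_U3` is the block-diagonal
#' deferred-measurement form \eqn{|0\rangle\langle 0| \otimes U3(b_0) +
#' |1\rangle\langle 1| \otimes U3(b_1)}.
#'
#' @param spec A [gate_spec()].
#' @return A complex matrix, unitary to machine precision.
#' @examples
#' gate_matrix(gate_spec("U3", 0, c(0, 0, 0)))  # identity
#' @export
gate_matrix <- function(spec) {
  stopifnot(inherits(spec, "gate_spec"))
  p <- spec$params
  switch(spec$kind,
    U3 = .u3_matrix(p[1], p[2], p[3]),
    RY = {
      c2 <- cos(p / 2); s2 <- sin(p / 2)
      matrix(c(c2, s2, -s2, c2), 2, 2) + 0i
    },
    RZ = diag(c(exp(-1i * p / 2), exp(1i * p / 2))),
    RX = {
      c2 <- cos(p / 2); s2 <- sin(p / 2)
      matrix(c(c2, -1i * s2, -1i * s2, c2), 2, 2)
    },
    CNOT = matrix(as.complex(c(1, 0, 0, 0,
                               0, 1, 0, 0,
                               0, 0, 0, 1,
                               0, 0, 1, 0)), 4, 4, byrow = TRUE),
    IsingXX = {
      c2 <- cos(p / 2); s2 <- -1i * sin(p / 2)
      m <- diag(rep(c2 + 0i, 4))
      m[1, 4] <- m[4, 1] <- m[2, 3] <- m[3, 2] <- s2
      m
    },
    COND_U3 = {
      m <- matrix(0i, 4, 4)
      m[1:2, 1:2] <- .u3_matrix(p[1], p[2], p[3])
      m[3:4, 3:4] <- .u3_matrix(p[4], p[5], p[6])
      m
    },
    stop(sprintf("unsupported gate kind '%s'", spec$kind)))
}

.u3_matrix <- function(theta, phi, delta) {
  c2 <- cos(theta / 2); s2 <- sin(theta / 2)
  matrix(c(c2, exp(1i * phi) * s2,
           -exp(1i * delta) * s2, exp(1i * (delta + phi)) * c2), 2, 2)
}

# Entry-wise derivative of the gate matrix with respect to parameter `which`.
# Used by the adjoint (reverse-mode) differentiation in the engine.
gate_matrix_deriv <- function(spec, which) {
  p <- spec$params
  stopifnot(which >= 1, which <= length(p))
  switch(spec$kind,
    U3 = .u3_deriv(p[1], p[2], p[3], which),
    RY = {
      c2 <- cos(p / 2) / 2; s2 <- sin(p / 2) / 2
      matrix(c(-s2, c2, -c2, -s2), 2, 2) + 0i
    },
    RZ = diag(c(-0.5i * exp(-1i * p / 2), 0.5i * exp(1i * p / 2))),
    RX = {
      c2 <- cos(p / 2) / 2; s2 <- sin(p / 2) / 2
      matrix(c(-s2, -1i * c2, -1i * c2, -s2), 2, 2)
    },
    IsingXX = {
      dc <- -sin(p / 2) / 2; ds <- -1i * cos(p / 2) / 2
      m <- diag(rep(dc + 0i, 4))
      m[1, 4] <- m[4, 1] <- m[2, 3] <- m[3, 2] <- ds
      m
    },
    COND_U3 = {
      m <- matrix(0i, 4, 4)
      if (which <= 3) m[1:2, 1:2] <- .u3_deriv(p[1], p[2], p[3], which)
      else m[3:4, 3:4] <- .u3_deriv(p[4], p[5], p[6], which - 3L)
      m
    },
    stop(sprintf("gate %s has no parameters", spec$kind)))
}

.u3_deriv <- function(theta, phi, delta, which) {
  c2 <- cos(theta / 2); s2 <- sin(theta / 2)
  if (which == 1L)
    matrix(c(-s2 / 2, exp(1i * phi) * c2 / 2,
             -exp(1i * delta) * c2 / 2, -exp(1i * (delta + phi)) * s2 / 2), 2, 2)
  else if (which == 2L)
    matrix(c(0, 1i * exp(1i * phi) * s2,
             0, 1i * exp(1i * (delta + phi)) * c2), 2, 2)
  else
    matrix(c(0, 0,
             -1i * exp(1i * delta) * s2, 1i * exp(1i * (delta + phi)) * c2), 2, 2)
}
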