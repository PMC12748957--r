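#' Pure n-qubit quantum state
#'
#' A statevector of `2^n_qubits` complex amplitudes with unit L2 norm.
#' Basis-index convention: qubit 0 is the most significant bit of the basis
#' index, so for 2 qubits the amplitudes are ordered
#' \eqn{|00\rangle, |01\rangle, |10\rangle, |11\rangle} with qubit 0 the left
#' bit. This convention is fixed package-wide and enforced by the oracle
#' tests.
#'
#' @param n_qubits Positive integer number of qubits.
#' @param amplitudes Optional complex vector of length `2^n_qubits`; defaults
#'   to the all-zero basis state \eqn{|0\cdots0\rangle}. Must have unit norm
#'   within `1e-9`.
#' @return An object of class `qstate`.
#' @examples
#' qstate(2)
#' qstate(1, c(1, 1) / sqrt(2))
#' @export
qstate <- function(n_qubits, amplitudes = NULL) {
  n_qubits <- as.integer(n_qubits)
  stopifnot(n_qubits >= 1L)
  dim_ <- 2L^n_qubits
  if (is.null(amplitudes)) {
    amplitudes <- complex(dim_)
    amplitudes[1] <- 1 + 0i
  } else {
    amplitudes <- as.complex(amplitudes)
    if (length(amplitudes) != dim_)
      stop(sprintf("expected %d amplitudes for %d qubits, got %d",
                   dim_, n_qubits, length(amplitudes)))
    nrm <- sqrt(sum(Mod(amplitudes)^2))
    if (abs(nrm - 1) > 1e-9)
      stop(sprintf("state norm %.3g is not 1 within 1e-9", nrm))
  }
  structure(list(n_qubits = n_qubits, amplitudes = amplitudes),
            class = "qstate")
}

#' @export
print.qstate <- function(x, ...) {
  cat(sprintf("<qstate %d qubit(s)>\n", x$n_qubits))
  amp <- x$amplitudes
  lab <- vapply(seq_along(amp) - 1L, function(i)
    paste(rev(as.integer(intToBits(i))[seq_len(x$n_qubits)]), collapse = ""),
    character(1))
  show <- Mod(amp) > 1e-12
  if (!any(show)) show[1] <- TRUE
  for (i in which(show))
    cat(sprintf("  |%s>  %s\n", lab[i], format(signif(amp[i], 4))))
  invisible(x)
}

# ---- batched column indexing ---------------------------------------------
# States are internally (rows x 2^n) complex matrices; one row per batch
# element. These helpers return 1-based column index groups for a gate's
# support under the qubit-0-is-MSB convention.

.pair_cols <- function(n, w) {
  s <- bitwShiftL(1L, n - 1L - w)
  idx <- 0:(2L^n - 1L)
  c0 <- idx[bitwAnd(idx, s) == 0L]
  list(c0 = c0 + 1L, c1 = c0 + s + 1L)
}

.quad_cols <- function(n, w1, w2) {
  s1 <- bitwShiftL(1L, n - 1L - w1)
  s2 <- bitwShiftL(1L, n - 1L - w2)
  idx <- 0:(2L^n - 1L)
  g00 <- idx[bitwAnd(idx, s1) == 0L & bitwAnd(idx, s2) == 0L]
  list(g00 = g00 + 1L, g01 = g00 + s2 + 1L,
       g10 = g00 + s1 + 1L, g11 = g00 + s1 + s2 + 1L)
}

# Apply a 2x2 operator with (possibly per-row) entries a,b,c,d to columns
# (c0, c1) of batched state A. Scalar entries are shared across rows,
# length-nrow entries give every batch row its own coefficient. Compiled
# hot path (src/engine.cpp). `inplace = TRUE` mutates A without copying;
# callers use it only on matrices they solely own.
.bapply_1q <- function(A, c0, c1, a, b, c, d, inplace = FALSE) {
  cpp_apply_1q(A, c0, c1, a, b, c, d, inplace)
}

# IsingXX-shaped operator: value `dg` on the diagonal, `off` on the
# anti-diagonal pairs (00,11) and (01,10).
.bapply_xxpair <- function(A, q, dg, off, inplace = FALSE) {
  cpp_apply_xxpair(A, q$g00, q$g01, q$g10, q$g11, dg, off, inplace)
}

.bapply_cnot <- function(A, q, inplace = FALSE) {
  cpp_apply_cnot(A, q$g10, q$g11, inplace)
}

# Two-branch controlled single-qubit operator (deferred measurement): branch
# entries e0/e1 are lists (a,b,c,d) applied in the control-0 / control-1
# subspaces respectively.
.bapply_block1q <- function(A, q, e0, e1, inplace = FALSE) {
  A <- .bapply_1q(A, q$g00, q$g01, e0$a, e0$b, e0$c, e0$d, inplace)
  .bapply_1q(A, q$g10, q$g11, e1$a, e1$b, e1$c, e1$d, inplace = TRUE)
}

.u3_entries <- function(theta, phi, delta) {
  c2 <- cos(theta / 2); s2 <- sin(theta / 2)
  list(a = c2 + 0i, b = -exp(1i * delta) * s2,
       c = exp(1i * phi) * s2, d = exp(1i * (delta + phi)) * c2)
}

.conj_t_entries <- function(e) {
  list(a = Conj(e$a), b = Conj(e$c), c = Conj(e$b), d = Conj(e$d))
}

# Batched application of one gate; params may be a numeric vector (shared
# across rows) or a matrix-like list of per-row vectors. `adj = TRUE` applies
# the conjugate transpose.
.bapply_gate <- function(A, n, kind, wires, params, adj = FALSE,
                         inplace = FALSE) {
  switch(kind,
    RY = {
      p <- params[[1]]; if (adj) p <- -p
      cp <- .pair_cols(n, wires[1])
      c2 <- cos(p / 2); s2 <- sin(p / 2)
      .bapply_1q(A, cp$c0, cp$c1, c2, -s2, s2, c2, inplace)
    },
    RZ = {
      p <- params[[1]]; if (adj) p <- -p
      cp <- .pair_cols(n, wires[1])
      .bapply_1q(A, cp$c0, cp$c1, exp(-1i * p / 2), 0, 0, exp(1i * p / 2),
                 inplace)
    },
    RX = {
      p <- params[[1]]; if (adj) p <- -p
      cp <- .pair_cols(n, wires[1])
      c2 <- cos(p / 2); s2 <- -1i * sin(p / 2)
      .bapply_1q(A, cp$c0, cp$c1, c2, s2, s2, c2, inplace)
    },
    U3 = {
      cp <- .pair_cols(n, wires[1])
      e <- .u3_entries(params[[1]], params[[2]], params[[3]])
      if (adj) e <- .conj_t_entries(e)
      .bapply_1q(A, cp$c0, cp$c1, e$a, e$b, e$c, e$d, inplace)
    },
    CNOT = .bapply_cnot(A, .quad_cols(n, wires[1], wires[2]), inplace),
    IsingXX = {
      p <- params[[1]]; if (adj) p <- -p
      q <- .quad_cols(n, wires[1], wires[2])
      .bapply_xxpair(A, q, cos(p / 2) + 0i, -1i * sin(p / 2), inplace)
    },
    COND_U3 = {
      q <- .quad_cols(n, wires[1], wires[2])
      e0 <- .u3_entries(params[[1]], params[[2]], params[[3]])
      e1 <- .u3_entries(params[[4]], params[[5]], params[[6]])
      if (adj) { e0 <- .conj_t_entries(e0); e1 <- .conj_t_entries(e1) }
      .bapply_block1q(A, q, e0, e1, inplace)
    },
    stop(sprintf("unsupported gate kind '%s'", kind)))
}

# ---- public single-state operations --------------------------------------

#' Apply a gate to a quantum state
#'
#' Contracts the gate's unitary into the statevector on the gate's wires.
#' Equivalent to multiplying by the identity-Kronecker expansion of
#' [gate_matrix()] but in O(2^n) per gate rather than O(4^n).
#'
#' @param state A [qstate()].
#' @param spec A [gate_spec()]; all wires must be `< state$n_qubits`.
#' @return The transformed `qstate` (norm preserved).
#' @examples
#' apply_gate(qstate(2, c(0, 0, 1, 0)), gate_spec("CNOT", c(0, 1)))
#' @export
apply_gate <- function(state, spec) {
  stopifnot(inherits(state, "qstate"), inherits(spec, "gate_spec"))
  if (any(spec$wires >= state$n_qubits))
    stop(sprintf("gate wires (%s) out of range for %d qubits",
                 paste(spec$wires, collapse = ","), state$n_qubits))
  A <- matrix(state$amplitudes, nrow = 1)
  A <- .bapply_gate(A, state$n_qubits, spec$kind, spec$wires,
                    as.list(spec$params))
  qstate(state$n_qubits, A[1, ])
}

#' Pauli-Z expectation of one qubit
#'
#' Born-rule expectation \eqn{\langle Z_w \rangle = \sum_i |a_i|^2 (+1
#' \textrm{ if bit } w \textrm{ of } i \textrm{ is } 0 \textrm{ else } -1)},
#' always in \eqn{[-1, 1]}. This is the real-valued readout used by all
#' classifier circuits in the package.
#'
#' @param state A [qstate()].
#' @param wire Qubit index (0-based).
#' @return A real number in `[-1, 1]`.
#' @examples
#' expect_z(qstate(1, c(0, 1)), 0)  # -1
#' @export
expect_z <- function(state, wire) {
  stopifnot(inherits(state, "qstate"), wire >= 0, wire < state$n_qubits)
  z <- .zsign(state$n_qubits, wire)
  sum(Mod(state$amplitudes)^2 * z)
}

.zsign <- function(n, w) {
  s <- bitwShiftL(1L, n - 1L - as.integer(w))
  ifelse(bitwAnd(0:(2L^n - 1L), s) == 0L, 1, -1)
}

#' Angle embedding of features as RY rotations
#'
#' Encodes one feature per qubit as \eqn{\prod_i RY(f_i)} applied to
#' \eqn{|0\cdots0\rangle}. Inputs must lie in `[0, pi]`: the RY embedding is
#' periodic in \eqn{2\pi}, so the half-period range prevents distinct values
#' from aliasing onto the same state.
#'
#' @param features Numeric vector of length `n_qubits`, values in `[0, pi]`.
#' @param n_qubits Number of qubits.
#' @return A [qstate()].
#' @examples
#' angle_embed(c(0, 0), 2)  # |00>
#' @export
angle_embed <- function(features, n_qubits) {
  n_qubits <- as.integer(n_qubits)
  if (length(features) != n_qubits)
    stop(sprintf("need %d features for %d qubits, got %d",
                 n_qubits, n_qubits, length(features)))
  if (any(features < 0 | features > pi))
    stop("angle-embedding features must lie in [0, pi]")
  st <- qstate(n_qubits)
  for (i in seq_len(n_qubits))
    st <- apply_gate(st, gate_spec("RY", i - 1L, features[i]))
  st
}

#' Amplitude embedding of a real vector
#'
#' Zero-pads the vector at the tail to length `2^n_qubits` and L2-normalizes
#' it into the statevector amplitudes. The number of padding zeros is
#' attached as attribute `pad_count` (e.g. 250 features on 8 qubits pad 6).
#'
#' @param vector Real vector, not all zero, of length at most `2^n_qubits`.
#' @param n_qubits Number of qubits.
#' @return A [qstate()] with attribute `pad_count`.
#' @examples
#' attr(amplitude_embed(rep(1, 250), 8), "pad_count")  # 6
#' @export
amplitude_embed <- function(vector, n_qubits) {
  n_qubits <- as.integer(n_qubits)
  dim_ <- 2L^n_qubits
  if (length(vector) < 1L || length(vector) > dim_)
    stop(sprintf("vector of length %d exceeds capacity %d of %d qubits",
                 length(vector), dim_, n_qubits))
  nrm <- sqrt(sum(vector^2))
  if (nrm == 0)
    stop("cannot amplitude-embed an all-zero vector")
  amp <- c(vector / nrm, numeric(dim_ - length(vector)))
  st <- qstate(n_qubits, amp)
  attr(st, "pad_count") <- dim_ - length(vector)
  st
}

#' Quantum pooling by measurement-conditioned U3
#'
#' Implements the pooling primitive "measure one qubit, condition a U3 on the
#' outcome" by deferred measurement: a two-branch controlled operation that
#' applies `U3(branch_params[1:3])` to the target when the measured wire is
#' \eqn{|0\rangle} and `U3(branch_params[4:6])` when it is \eqn{|1\rangle}.
#' The state stays pure and differentiable; for any later Z-expectation on
#' wires other than `measured_wire` the result equals the probability-weighted
#' average over explicitly collapsing the measured wire and applying the
#' corresponding branch (deferred-measurement principle).
#'
#' @param state A [qstate()].
#' @param measured_wire Wire whose measurement outcome conditions the gate.
#' @param target_wire Wire the conditional U3 acts on; must differ.
#' @param branch_params Numeric length 6: U3 angles for the \eqn{|0\rangle}
#'   branch then the \eqn{|1\rangle} branch.
#' @return The pooled [qstate()].
#' @export
pool_conditional_u3 <- function(state, measured_wire, target_wire,
                                branch_params) {
  if (measured_wire == target_wire)
    stop("measured_wire and target_wire must differ")
  apply_gate(state, gate_spec("COND_U3", c(measured_wire, target_wire),
                              branch_params))
}

# ---- circuits -------------------------------------------------------------

#' An ordered gate list with Z readout wires
#'
#' @param n_qubits Number of qubits.
#' @param gates List of [gate_spec()] objects.
#' @param readout Integer vector of distinct wires whose Pauli-Z expectations
#'   form the circuit output.
#' @return An object of class `qcircuit`.
#' @export
qcircuit <- function(n_qubits, gates = list(), readout = integer(0)) {
  n_qubits <- as.integer(n_qubits)
  stopifnot(n_qubits >= 1L)
  for (g in gates) {
    stopifnot(inherits(g, "gate_spec"))
    if (any(g$wires >= n_qubits))
      stop("gate wire out of range for circuit")
  }
  readout <- as.integer(readout)
  if (anyDuplicated(readout) || any(readout < 0L | readout >= n_qubits))
    stop("readout wires must be distinct and valid")
  structure(list(n_qubits = n_qubits, gates = gates, readout = readout),
            class = "qcircuit")
}

#' @export
print.qcircuit <- function(x, ...) {
  cat(sprintf("<qcircuit %d qubits, %d gates, readout Z(%s)>\n",
              x$n_qubits, length(x$gates),
              paste(x$readout, collapse = ",")))
  invisible(x)
}

#' Run a circuit on a state
#'
#' @param circuit A [qcircuit()].
#' @param state Optional initial [qstate()]; defaults to
#'   \eqn{|0\cdots0\rangle}.
#' @return A list with `state` (final [qstate()]) and `readout` (numeric
#'   vector of Z expectations on the circuit's readout wires).
#' @export
run_circuit <- function(circuit, state = NULL) {
  stopifnot(inherits(circuit, "qcircuit"))
  if (is.null(state)) state <- qstate(circuit$n_qubits)
  stopifnot(state$n_qubits == circuit$n_qubits)
  for (g in circuit$gates) state <- apply_gate(state, g)
  list(state = state,
       readout = vapply(circuit$readout, function(w) expect_z(state, w),
                        numeric(1)))
}

#' Serialize a circuit to plain text
#'
#' One gate per line: `kind wires... | params...`, plus header lines for the
#' qubit count and readout wires. Round-trips exactly through
#' [circuit_from_text()] (parameters at full precision).
#'
#' @param circuit A [qcircuit()].
#' @return A character vector of lines.
#' @export
circuit_to_text <- function(circuit) {
  stopifnot(inherits(circuit, "qcircuit"))
  hdr <- c(sprintf("qubits %d", circuit$n_qubits),
           sprintf("readout %s", paste(circuit$readout, collapse = " ")))
  body <- vapply(circuit$gates, function(g) {
    paste(c(g$kind, g$wires,
            if (length(g$params)) c("|", sprintf("%.17g", g$params))),
          collapse = " ")
  }, character(1))
  c(hdr, body)
}

#' Parse a circuit from its plain-text form
#'
#' @param lines Character vector as produced by [circuit_to_text()].
#' @return A [qcircuit()].
#' @export
circuit_from_text <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  if (toks[[1]][1] != "qubits") stop("malformed circuit text: no qubit header")
  n <- as.integer(toks[[1]][2])
  ro <- integer(0)
  start <- 2L
  if (length(toks) >= 2L && toks[[2]][1] == "readout") {
    ro <- as.integer(toks[[2]][-1])
    start <- 3L
  }
  gates <- list()
  if (length(toks) >= start) {
    for (tk in toks[seq(start, length(toks))]) {
      bar <- match("|", tk)
      if (is.na(bar)) {
        wires <- as.integer(tk[-1]); params <- numeric(0)
      } else {
        wires <- as.integer(tk[2:(bar - 1)])
        params <- as.numeric(tk[(bar + 1):length(tk)])
      }
      gates[[length(gates) + 1L]] <- gate_spec(tk[1], wires, params)
    }
  }
  qcircuit(n, gates, ro)
}
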