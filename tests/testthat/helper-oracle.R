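# Independent brute-force oracles. These deliberately avoid the package's
# column-pair update path: gates are expanded to dense 2^n x 2^n unitaries
# (identity-Kronecker for single-qubit gates, entrywise bit bookkeeping for
# two-qubit gates) and applied by full matrix multiplication.

bit_of <- function(i, n, w) bitwAnd(bitwShiftR(i, n - 1L - w), 1L)

# Dense 2^n x 2^n matrix of a gate acting on spec$wires (qubit 0 = MSB).
dense_gate_full <- function(n, spec) {
  G <- gate_matrix(spec)
  if (length(spec$wires) == 1L) {
    w <- spec$wires[1]
    kronecker(diag(2^w), kronecker(G, diag(2^(n - 1L - w))))
  } else {
    w1 <- spec$wires[1]; w2 <- spec$wires[2]
    dim_ <- 2L^n
    M <- matrix(0i, dim_, dim_)
    for (i in 0:(dim_ - 1L)) for (j in 0:(dim_ - 1L)) {
      # rows/cols agree on every qubit outside the gate's support
      same <- TRUE
      for (w in 0:(n - 1L)) {
        if (w == w1 || w == w2) next
        if (bit_of(i, n, w) != bit_of(j, n, w)) { same <- FALSE; break }
      }
      if (same) {
        gi <- 2L * bit_of(i, n, w1) + bit_of(i, n, w2)
        gj <- 2L * bit_of(j, n, w1) + bit_of(j, n, w2)
        M[i + 1L, j + 1L] <- G[gi + 1L, gj + 1L]
      }
    }
    M
  }
}

dense_run <- function(circuit, amplitudes = NULL) {
  v <- amplitudes %||% c(1, rep(0, 2^circuit$n_qubits - 1))
  for (g in circuit$gates)
    v <- dense_gate_full(circuit$n_qubits, g) %*% v
  drop(v)
}

# <psi| Z_w |psi> via the dense observable sandwich.
dense_zexp <- function(n, wire, v) {
  z <- diag((-1)^vapply(0:(2^n - 1L), bit_of, integer(1), n = n, w = wire))
  Re(drop(Conj(v) %*% z %*% v))
}

# Explicit two-branch collapse-and-average oracle for quantum pooling:
# measure `m`, collapse, apply the outcome's U3 on `t`, then average the
# downstream Z expectation over outcomes weighted by the Born probabilities.
collapse_pool_zexp <- function(state, m, t, branch_params, readout_wire) {
  n <- state$n_qubits
  amp <- state$amplitudes
  bits <- vapply(seq_along(amp) - 1L, bit_of, integer(1), n = n, w = m)
  total <- 0
  for (outcome in 0:1) {
    sel <- bits == outcome
    p <- sum(Mod(amp[sel])^2)
    if (p < 1e-15) next
    collapsed <- ifelse(sel, amp, 0i) / sqrt(p)
    u3 <- gate_spec("U3", t, branch_params[outcome * 3L + 1:3])
    after <- dense_gate_full(n, u3) %*% collapsed
    total <- total + p * dense_zexp(n, readout_wire, drop(after))
  }
  total
}

# Central finite differences (the gradient contract's independent oracle).
fd_grad <- function(f, x, h = 1e-4) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- x[i] + h
    xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random circuit over the full gate set.
rand_circuit <- function(n, n_gates, readout = 0L) {
  kinds <- c("U3", "RY", "RZ", "RX", "CNOT", "IsingXX", "COND_U3")
  nparams <- c(U3 = 3, RY = 1, RZ = 1, RX = 1, CNOT = 0, IsingXX = 1,
               COND_U3 = 6)
  gates <- lapply(seq_len(n_gates), function(i) {
    k <- if (n == 1L) sample(c("U3", "RY", "RZ", "RX"), 1) else
      sample(kinds, 1)
    wires <- if (k %in% c("CNOT", "IsingXX", "COND_U3"))
      sample(0:(n - 1L), 2) else sample(0:(n - 1L), 1)
    gate_spec(k, wires, runif(nparams[[k]], -pi, pi))
  })
  qcircuit(n, gates, readout = readout)
}

rand_state <- function(n) {
  v <- complex(real = rnorm(2^n), imaginary = rnorm(2^n))
  qstate(n, v / sqrt(sum(Mod(v)^2)))
}
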