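test_that("statevector engine agrees with the dense Kronecker oracle", {
  set.seed(202)
  for (rep in 1:30) {
    n <- sample(1:4, 1)
    circ <- rand_circuit(n, 12)
    fast <- run_circuit(circ)$state$amplitudes
    dense <- dense_run(circ)
    expect_lt(max(Mod(fast - dense)), 1e-10)
  }
})

test_that("apply_gate preserves the norm over long random circuits", {
  set.seed(203)
  for (rep in 1:3) {
    circ <- rand_circuit(4, 50)
    st <- run_circuit(circ)$state
    expect_lt(abs(sqrt(sum(Mod(st$amplitudes)^2)) - 1), 1e-10)
  }
})

test_that("qstate validates length and norm; apply_gate validates wires", {
  expect_error(qstate(2, c(1, 0)), "expected 4 amplitudes")
  expect_error(qstate(1, c(1, 1)), "norm")
  expect_error(apply_gate(qstate(1), gate_spec("CNOT", c(0, 1))),
               "out of range")
})

test_that("expect_z matches the computational basis and the dense sandwich", {
  expect_equal(expect_z(qstate(1, c(1, 0)), 0), 1)
  expect_equal(expect_z(qstate(1, c(0, 1)), 0), -1)
  expect_equal(expect_z(qstate(1, c(1, 1) / sqrt(2)), 0), 0)
  set.seed(204)
  for (rep in 1:20) {
    n <- sample(1:4, 1)
    st <- rand_state(n)
    w <- sample(0:(n - 1L), 1)
    expect_equal(expect_z(st, w), dense_zexp(n, w, st$amplitudes),
                 tolerance = 1e-12)
    expect_lte(abs(expect_z(st, w)), 1)
  }
})

test_that("angle embedding composes RY rotations and enforces its range", {
  expect_equal(angle_embed(c(0, 0, 0), 3)$amplitudes[1], 1 + 0i)
  # pi on one qubit gives |1> up to global sign
  st <- angle_embed(pi, 1)
  expect_lt(Mod(st$amplitudes[1]), 1e-12)
  expect_equal(Mod(st$amplitudes[2]), 1)
  # compositional oracle: embedding equals the explicit RY chain
  set.seed(205)
  f <- runif(3, 0, pi)
  manual <- qstate(3)
  for (i in 1:3) manual <- apply_gate(manual, gate_spec("RY", i - 1L, f[i]))
  expect_equal(angle_embed(f, 3)$amplitudes, manual$amplitudes)
  expect_error(angle_embed(c(0, 4), 2), "\\[0, pi\\]")
  expect_error(angle_embed(c(-0.1, 1), 2), "\\[0, pi\\]")
  expect_error(angle_embed(1, 2), "2 features")
})

test_that("amplitude embedding pads at the tail and normalizes", {
  st <- amplitude_embed(rep(1, 250), 8)
  expect_equal(attr(st, "pad_count"), 6L)
  expect_equal(sum(Mod(st$amplitudes)^2), 1, tolerance = 1e-12)
  expect_equal(Mod(st$amplitudes[251:256]), rep(0, 6))
  expect_equal(attr(amplitude_embed(rep(1, 54), 6), "pad_count"), 10L)
  expect_equal(amplitude_embed(c(1, 1, 1, 1), 2)$amplitudes,
               rep(0.5 + 0i, 4))
  expect_error(amplitude_embed(numeric(0), 2), "length")
  expect_error(amplitude_embed(rep(0, 4), 2), "all-zero")
  expect_error(amplitude_embed(rep(1, 5), 2), "capacity")
})

test_that("circuits serialize to text and back exactly", {
  set.seed(206)
  circ <- rand_circuit(3, 8, readout = c(0L, 2L))
  back <- circuit_from_text(circuit_to_text(circ))
  expect_equal(back$n_qubits, circ$n_qubits)
  expect_equal(back$readout, circ$readout)
  for (i in seq_along(circ$gates)) {
    expect_identical(back$gates[[i]]$kind, circ$gates[[i]]$kind)
    expect_identical(back$gates[[i]]$wires, circ$gates[[i]]$wires)
    expect_identical(back$gates[[i]]$params, circ$gates[[i]]$params)
  }
  expect_equal(run_circuit(back)$readout, run_circuit(circ)$readout)
})

test_that("the Bell fixture produces the expected amplitudes", {
  fx <- toy_fixtures()
  st <- run_circuit(fx$bell_circuit)$state
  expect_equal(st$amplitudes, fx$bell_amplitudes + 0i, tolerance = 1e-12)
})
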