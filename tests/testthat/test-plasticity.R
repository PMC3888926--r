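test_that("the four LTP/LTD branches match a literal conditional oracle", {
  p <- plasticity_params(delta_w = 0.01, theta_pre = 0.1, theta_plus = 0.3,
                         theta_minus = 0.05, w_max = 1)
  oracle <- function(w, o, v) {
    if (o >= p$theta_pre && v >= p$theta_plus) w <- w + p$delta_w
    else if (o >= p$theta_pre && v >= p$theta_minus && v < p$theta_plus)
      w <- w - p$delta_w
    else if (o < p$theta_pre && v >= p$theta_plus) w <- w - p$delta_w
    min(max(w, 0), p$w_max)
  }
  grid <- expand.grid(
    o = c(0, 0.05, 0.1 - 1e-9, 0.1, 0.2, 1),
    v = c(-1, 0, 0.05 - 1e-9, 0.05, 0.1, 0.3 - 1e-9, 0.3, 0.5, 2),
    w = c(0, 0.005, 0.5, 0.995, 1)
  )
  got <- hebbian_update(grid$w, grid$o, grid$v, p)
  want <- mapply(oracle, grid$w, grid$o, grid$v)
  expect_equal(got, want)
})

test_that("boundary cases follow the rule exactly", {
  p <- plasticity_params(delta_w = 0.02, theta_pre = 0.1, theta_plus = 0.3,
                         theta_minus = 0.05, w_max = 1)
  # boundaries are inclusive for LTP ...
  expect_equal(hebbian_update(0.5, p$theta_pre, p$theta_plus, p), 0.52)
  # ... LTD at exactly theta_minus with an active presynaptic link
  expect_equal(hebbian_update(0.5, p$theta_pre, p$theta_minus, p), 0.48)
  # inactive link onto a moderately depolarised cell: unchanged
  expect_equal(hebbian_update(0.5, 0.05, 0.1, p), 0.5)
  # clipping
  expect_equal(hebbian_update(0.01, 1, 0.1, p), 0)
  expect_equal(hebbian_update(0.999, 1, 1, p), 1)
})

test_that("disabled plasticity and quiescent networks leave weights alone", {
  net <- tiny_net(grid = c(5, 5), seed = 10)
  dyn <- dynamics_params()
  set.seed(2)
  off <- simulate_network(net, init_state(net), dyn, 50,
                          plasticity = plasticity_params(enabled = FALSE))
  expect_identical(off$net$W_ee@x, net$W_ee@x)

  # all-quiescent network (no noise, zero state): otherwise-branch everywhere
  dyn0 <- dynamics_params(k2 = 0)
  on <- simulate_network(net, init_state(net), dyn0, 50,
                         plasticity = plasticity_params())
  expect_identical(on$net$W_ee@x, net$W_ee@x)
})

test_that("engine plasticity equals the R rule applied per step", {
  net <- tiny_net(grid = c(4, 4), seed = 11)
  dyn <- dynamics_params(k2 = 3, alpha = 2)
  pl <- plasticity_params(delta_w = 0.01, theta_pre = 0.1, theta_plus = 0.2,
                          theta_minus = 0.02, w_max = 0.3)
  n <- 12
  set.seed(21)
  eng <- simulate_network(net, init_state(net), dyn, n, plasticity = pl)
  # replay with the reference stepper, applying the R rule with O(t), V(t)
  set.seed(21)
  st <- init_state(net)
  ref <- net
  for (i in seq_len(n)) {
    out <- step_reference(ref, st, dyn)
    snap <- st; snap$O_e <- out$O_e  # outputs used at step t
    ref <- apply_plasticity(ref, snap, pl)
    st <- out$state
  }
  expect_equal(eng$net$W_ee@x, ref$W_ee@x, tolerance = 1e-12)
})

test_that("co-driven cells gain exactly k * delta_w per step of LTP", {
  # two mutually linked cells held above all thresholds for k steps
  net <- tiny_net(grid = c(4, 4), seed = 12)
  pl <- plasticity_params(delta_w = 0.003, theta_pre = 0.5, theta_plus = 0.5,
                          theta_minus = 0.1, w_max = 2)
  dyn <- dynamics_params(k2 = 0)
  # pick a realised within-P1 edge so the weight actually exists
  tr <- Matrix::summary(net$W_ee)
  within_p1 <- which(tr$i <= net$n_cells & tr$j <= net$n_cells)[1]
  cells <- c(tr$i[within_p1], tr$j[within_p1])
  w0 <- net$W_ee[cells[1], cells[2]]
  expect_gt(w0, 0)
  k <- 8
  set.seed(1)
  out <- simulate_network(net, init_state(net), dyn, k,
                          stim_cells = cells, stim_amp = 50,
                          plasticity = pl)
  w1 <- out$net$W_ee[cells[1], cells[2]]
  # cells reach V >= theta_plus from step 2 on (state at step 1 is rest) and
  # output 1 follows one step later; count steps satisfying both conditions
  set.seed(1)
  st <- init_state(net)
  n_ltp <- 0
  for (i in seq_len(k)) {
    o <- excitatory_output(st$V_e[cells[1]], dyn$alpha * st$omega[cells[1]])
    if (o >= pl$theta_pre && st$V_e[cells[2]] >= pl$theta_plus) {
      n_ltp <- n_ltp + 1
    }
    st <- step_reference(net, st, dyn, cells, 50)$state
  }
  expect_equal(w1 - w0, n_ltp * pl$delta_w, tolerance = 1e-12)
  expect_gt(n_ltp, 0)
})

test_that("weights stay in [0, w_max] along noisy plastic trajectories", {
  net <- tiny_net(grid = c(5, 5), seed = 13)
  pl <- plasticity_params(delta_w = 0.05, theta_pre = 0.05, theta_plus = 0.1,
                          theta_minus = 0.01, w_max = 0.15)
  set.seed(31)
  out <- simulate_network(net, init_state(net), dynamics_params(k2 = 6), 400,
                          plasticity = pl)
  expect_true(all(out$net$W_ee@x >= 0))
  expect_true(all(out$net$W_ee@x <= pl$w_max))
  expect_true(any(out$net$W_ee@x != net$W_ee@x))  # plasticity actually acted
})

test_that("paired stimulation raises the paired-set weights above unpaired", {
  # monotone-association property on a 2-area-like toy: use P1 only
  net <- tiny_net(grid = c(6, 6), seed = 14)
  dyn <- dynamics_params(k2 = 1)
  pl <- plasticity_params(delta_w = 0.01, theta_pre = 0.1, theta_plus = 0.3,
                          theta_minus = 0.05, w_max = 0.5)
  set_a <- global_cells(net, "P1", 1:6)
  W <- net$W_ee
  pre_mean <- function(W, s) {
    x <- W[s, s]
    mean(x@x)
  }
  w_before <- pre_mean(W, set_a)
  st <- init_state(net)
  set.seed(41)
  for (rep in 1:25) {
    out <- simulate_network(net, st, dyn, 10, stim_cells = set_a,
                            stim_amp = 20, plasticity = pl)
    net <- out$net
    out <- simulate_network(net, out$state, dyn, 10, plasticity = pl)
    net <- out$net
    st <- out$state
  }
  w_after <- pre_mean(net$W_ee, set_a)
  expect_gt(w_after, w_before)
  # unpaired cells far from the stimulated set do not potentiate above
  # their initial mean (within one delta_w)
  far <- global_cells(net, "M1", 1:36)
  w_far <- pre_mean(net$W_ee, far)
  w_far0 <- pre_mean(W, far)
  expect_lt(w_far, w_far0 + pl$delta_w)
})
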