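# synthetic profile: responses set by hand per area/pattern
make_profile <- function(net, values) {
  # values: function(area_index) -> numeric(n_cells) for pattern 1, or a
  # matrix n_e x n_pat
  prof <- if (is.matrix(values)) values else {
    v <- unlist(lapply(seq_len(net$n_areas), values))
    matrix(v, ncol = 1)
  }
  structure(prof, areas = net$areas, n_cells = net$n_cells,
            class = c("ca_profile", "matrix", "array"))
}

test_that("membership thresholds are gamma times the per-area maximum", {
  net <- tiny_net(grid = c(4, 4), seed = 1)
  prof <- make_profile(net, function(a) seq(0, 0.75, length.out = 16) * a / 6)
  m <- identify_ca_cells(prof, gamma = 0.5)
  thr <- attr(m, "thresholds")
  for (a in seq_len(6)) {
    expect_equal(thr$theta[thr$area == net$areas$area[a]],
                 0.5 * 0.75 * a / 6)
  }
  # members are exactly the cells at or above threshold
  counts <- table(m$area)
  expect_true(all(counts == 8))  # values 0.40..0.75 reach half the max of 0.75
})

test_that("gamma = 1 keeps only the argmax cells and memberships nest", {
  net <- tiny_net(grid = c(5, 5), seed = 2)
  set.seed(3)
  prof <- make_profile(net, function(a) runif(25))
  m1 <- identify_ca_cells(prof, gamma = 1)
  expect_equal(nrow(m1), 6)  # one argmax cell per area
  m_50 <- identify_ca_cells(prof, gamma = 0.5)
  m_25 <- identify_ca_cells(prof, gamma = 0.25)
  key <- function(m) paste(m$pattern, m$area, m$cell)
  expect_true(all(key(m1) %in% key(m_50)))
  expect_true(all(key(m_50) %in% key(m_25)))
})

test_that("all-zero profiles yield empty, flagged CAs", {
  net <- tiny_net(grid = c(4, 4), seed = 3)
  prof <- make_profile(net, function(a) rep(0, 16))
  w <- testthat::capture_warnings(m <- identify_ca_cells(prof, 0.5))
  expect_length(w, 6)  # one flag per area
  expect_true(all(grepl("all-zero", w)))
  expect_equal(nrow(m), 0)
})

test_that("ca_size_table reports per-area means bounded by the grid", {
  net <- tiny_net(grid = c(5, 5), seed = 4)
  set.seed(5)
  prof <- make_profile(net, matrix(runif(net$n_e * 2), ncol = 2))
  tab <- ca_size_table(prof, gammas = c(0.1, 0.5))
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$mean_size <= 25))
  # single pattern, single gamma reduces to that membership's counts
  prof1 <- make_profile(net, matrix(prof[, 1], ncol = 1))
  m <- identify_ca_cells(prof1, 0.5)
  tab1 <- ca_size_table(prof1, gammas = 0.5)
  cnt <- table(m$area)
  for (a in names(cnt)) {
    expect_equal(tab1$mean_size[tab1$area == a], unname(cnt[a]))
  }
})

test_that("ignition detection matches the brute-force oracle", {
  net <- tiny_net(grid = c(4, 4), seed = 6)
  memb <- synthetic_membership(
    net,
    tibble::tibble(pattern = rep(1:2, each = 4),
                   area = rep(c("P1", "M1"), 4),
                   cell = c(1, 1, 2, 2, 3, 3, 4, 4)),
    theta = 0.5
  )
  set.seed(7)
  # random recording with values straddling the threshold
  rec <- hebbca:::new_ca_recording(
    matrix(runif(60 * net$n_e), 60, net$n_e), net
  )
  got <- detect_ignitions(rec, memb)
  want <- oracle_detect(rec, memb)
  expect_equal(got[, c("pattern", "onset", "offset")], want,
               ignore_attr = TRUE)
})

test_that("a single step at exactly 50% active is one event of length 1", {
  net <- tiny_net(grid = c(4, 4), seed = 8)
  memb <- synthetic_membership(
    net, tibble::tibble(pattern = 1, area = c("P1", "P1", "M1", "M1"),
                        cell = c(1, 2, 1, 2)), theta = 0.4)
  cells <- c(global_cells(net, "P1", 1), global_cells(net, "M1", 1))
  rec <- synthetic_recording(net, list(integer(0), cells, integer(0)),
                             level = 0.4)  # boundary: output == theta
  ev <- detect_ignitions(rec, memb)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset, 2)
  expect_equal(ev$offset, 2)
  # just below threshold: no event
  rec2 <- synthetic_recording(net, list(integer(0), cells, integer(0)),
                              level = 0.399)
  expect_equal(nrow(detect_ignitions(rec2, memb)), 0)
})

test_that("two CAs active in disjoint windows give two labelled events", {
  net <- tiny_net(grid = c(4, 4), seed = 9)
  memb <- synthetic_membership(
    net, tibble::tibble(pattern = rep(1:2, each = 2),
                        area = rep("P1", 4), cell = 1:4), theta = 0.5)
  ca1 <- global_cells(net, "P1", 1:2)
  ca2 <- global_cells(net, "P1", 3:4)
  rec <- synthetic_recording(
    net, c(rep(list(ca1), 3), list(integer(0)), rep(list(ca2), 2)))
  ev <- detect_ignitions(rec, memb)
  expect_equal(ev$pattern, c(1, 2))
  expect_equal(ev$onset, c(1, 5))
  expect_equal(ev$offset, c(3, 6))
  # merging across a 1-step gap when requested
  rec2 <- synthetic_recording(
    net, c(rep(list(ca1), 2), list(integer(0)), rep(list(ca1), 2)))
  expect_equal(nrow(detect_ignitions(rec2, memb, min_gap = 0)), 2)
  ev2 <- detect_ignitions(rec2, memb, min_gap = 1)
  expect_equal(nrow(ev2), 1)
  expect_equal(c(ev2$onset, ev2$offset), c(1, 5))
})

test_that("all-zero recordings contain no events", {
  net <- tiny_net(grid = c(4, 4), seed = 10)
  memb <- synthetic_membership(
    net, tibble::tibble(pattern = 1, area = "P1", cell = 1:2), theta = 0.1)
  rec <- synthetic_recording(net, rep(list(integer(0)), 30))
  expect_equal(nrow(detect_ignitions(rec, memb)), 0)
})

test_that("detection is idempotent", {
  net <- tiny_net(grid = c(4, 4), seed = 11)
  memb <- synthetic_membership(
    net, tibble::tibble(pattern = 1, area = "P1", cell = 1:3), theta = 0.3)
  set.seed(12)
  rec <- hebbca:::new_ca_recording(
    matrix(runif(40 * net$n_e), 40, net$n_e), net)
  e1 <- detect_ignitions(rec, memb)
  e2 <- detect_ignitions(rec, memb)
  expect_identical(e1, e2)
})

test_that("ASI of duplicated synthetic events equals the single trial", {
  net <- tiny_net(grid = c(4, 4), seed = 13)
  memb <- synthetic_membership(
    net, tibble::tibble(pattern = 1, area = c("P1", "P1", "M1", "M1"),
                        cell = c(1, 2, 1, 2)), theta = 0.5)
  ca <- c(global_cells(net, "P1", 1:2), global_cells(net, "M1", 1:2))
  # one stereotyped 6-step burst, repeated twice, well inside the recording
  burst <- function(at) {
    lapply(seq_len(100), function(t) {
      if (t >= at && t < at + 5) ca
      else if (t == at + 5) ca[c(1, 3)]  # one P1, one M1: still 50% active
      else integer(0)
    })
  }
  # trials far enough apart that their 40-step windows do not overlap
  b1 <- burst(15); b2 <- burst(58)
  both <- lapply(seq_len(100), function(t) union(b1[[t]], b2[[t]]))
  rec <- synthetic_recording(net, both)
  ev <- detect_ignitions(rec, memb)
  expect_equal(nrow(ev), 2)
  asi <- extract_asi(rec, ev, memb, pre = 10, len = 40)
  # two identical trials: the mean equals the common trial exactly
  p1 <- asi[asi$area == "P1", ]
  expect_equal(nrow(p1), 40)
  expect_equal(p1$count[p1$step == 0], 2)   # both P1 members active at onset
  expect_equal(p1$count[p1$step == 5], 1)   # the decaying tail step
  expect_equal(p1$count[p1$step == -1], 0)
  expect_true(all(asi$norm >= 0 & asi$norm <= 1))
  expect_equal(unique(asi$n_trials), 2)
  # single-event ASI equals that trial
  rec1 <- synthetic_recording(net, b1)
  ev1 <- detect_ignitions(rec1, memb)
  asi1 <- extract_asi(rec1, ev1, memb, pre = 10, len = 40)
  expect_equal(asi1$count[asi1$area == "P1"], p1$count)
})

test_that("events too close to the recording edges are dropped", {
  net <- tiny_net(grid = c(4, 4), seed = 14)
  memb <- synthetic_membership(
    net, tibble::tibble(pattern = 1, area = "P1", cell = 1:2), theta = 0.5)
  ca <- global_cells(net, "P1", 1:2)
  rec <- synthetic_recording(net, c(rep(list(ca), 3),
                                    rep(list(integer(0)), 30)))
  ev <- detect_ignitions(rec, memb)  # onset at 1: window would start at -9
  expect_equal(nrow(ev), 1)
  asi <- extract_asi(rec, ev, memb, pre = 10, len = 40)
  expect_equal(nrow(asi), 0)
})

test_that("baseline alignment finds the last all-zero step and shifts with it", {
  net <- tiny_net(grid = c(4, 4), seed = 15)
  memb <- synthetic_membership(
    net, tibble::tibble(pattern = rep(1:2, each = 4), area = rep("P1", 8),
                        cell = 1:8), theta = 0.5)
  mk <- function(shift) {
    lapply(seq_len(80), function(t) {
      on <- integer(0)
      # CA1: one of four cells (25%, below the 50% activity criterion) ramps
      # up 3 steps before the detected onset at t = 30 + shift
      if (t >= 27 + shift && t < 30 + shift) on <- global_cells(net, "P1", 1)
      if (t >= 30 + shift && t < 40 + shift) on <- global_cells(net, "P1", 1:3)
      if (t >= 31 + shift && t < 40 + shift)
        on <- c(on, global_cells(net, "P1", 5:8))
      on
    })
  }
  rec <- synthetic_recording(net, mk(0))
  ev <- detect_ignitions(rec, memb)
  expect_equal(ev$onset[ev$pattern == 1], 30)
  asi <- extract_asi(rec, ev, memb)
  win <- align_baseline(asi, window = 6)
  expect_equal(attr(win, "window"), 6L)
  expect_equal(sort(unique(win$step)), 0:5)
  # CA1's ramp cell appears 3 steps before onset, so the last all-zero step
  # is onset - 4
  expect_equal(attr(win, "origin"), -4L)
  # at the origin every value is zero
  expect_true(all(win$value[win$step == 0] == 0))
  # translation equivariance: shifting the recording shifts the origin with
  # it, leaving the aligned window unchanged
  rec2 <- synthetic_recording(net, mk(7))
  asi2 <- extract_asi(rec2, detect_ignitions(rec2, memb), memb)
  win2 <- align_baseline(asi2, window = 6)
  expect_equal(attr(win2, "origin"), -4L)
  expect_equal(win2$value, win$value)
})

test_that("alignment fails informatively when no baseline step exists", {
  net <- tiny_net(grid = c(4, 4), seed = 16)
  memb <- synthetic_membership(
    net, tibble::tibble(pattern = 1, area = "P1", cell = 1:2), theta = 0.5)
  ca <- global_cells(net, "P1", 1:2)
  # member cells always active: no all-zero pre-onset step
  rec <- synthetic_recording(net, c(rep(list(ca[1]), 20), rep(list(ca), 20),
                                    rep(list(integer(0)), 10)))
  ev <- detect_ignitions(rec, memb)
  asi <- extract_asi(rec, ev, memb)
  expect_error(align_baseline(asi), "no all-baseline step")
})
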