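# Synthetic-experiment generator: source space, atlas, lead field, schedule,
# pleasantness scores.

test_that("octahedron subdivision follows the 4^l + 2 vertex law", {
  # oracle on the explicit mesh: V_{n+1} = V_n + E_n; octahedron has
  # V = 6, E = 12, F = 8 and each subdivision maps E -> 2E + 3F, F -> 4F
  V <- 6; E <- 12; F <- 8
  for (l in 1:6) {
    expect_equal(V, 4^l + 2)
    Enew <- 2 * E + 3 * F
    V <- V + E; E <- Enew; F <- 4 * F
  }
  expect_equal(sum(build_source_space(1)$hemisphere == "left"), 6)
  expect_equal(sum(build_source_space(2)$hemisphere == "left"), 18)
  expect_equal(sum(build_source_space(6)$hemisphere == "left"), 4098)
})

test_that("source space geometry is valid", {
  ss <- fix_space3()
  expect_s3_class(ss, "source_space")
  # unit orientations
  expect_equal(sqrt(rowSums(ss$orientations^2)), rep(1, nrow(ss$vertices)),
               tolerance = 1e-12)
  # all vertices strictly inside the brain compartment
  expect_true(all(sqrt(rowSums(ss$vertices^2)) < head_geometry()$radii[1]))
  # closed mesh: every edge shared by exactly two faces
  f <- ss$faces_per_hemi
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) == 2))
  expect_error(build_source_space(0), "integer >= 1")
  expect_error(build_source_space(8), "refused")
})

test_that("atlas partitions every vertex into 68 named regions", {
  at5 <- build_atlas(build_source_space(5), seed = 2)
  expect_equal(nlevels(at5$label_of_vertex), 68)
  expect_equal(length(unique(at5$label_of_vertex)), 68)
  expect_false(any(is.na(at5$label_of_vertex)))    # exactly one label each
  expect_setequal(unique(sub("_(lh|rh)$", "", at5$region_names)),
                  dk_region_names())
})

test_that("pleasantness ROIs are non-empty and reproducible", {
  at <- fix_atlas3()
  for (r in pleasantness_rois())
    expect_gt(sum(at$label_of_vertex == r), 0)
  at2 <- build_atlas(fix_space3(), seed = 1)
  expect_identical(at$label_of_vertex, at2$label_of_vertex)
  # a different seed moves the free (non-canonical) regions
  at3 <- build_atlas(fix_space3(), seed = 99)
  expect_false(identical(at$label_of_vertex, at3$label_of_vertex))
  expect_error(build_atlas(build_source_space(2)), "fewer vertices")
})

test_that("spherical lead field obeys symmetry, linearity and reference rank", {
  fwd <- fix_forward3()
  ss <- fix_space3()
  G <- fwd$lead_field
  expect_true(all(is.finite(G)))
  expect_true(all(colSums(G^2) > 0))
  # rank of the average-referenced lead field
  H <- diag(64) - matrix(1 / 64, 64, 64)
  expect_gte(qr(H %*% G)$rank, 63)

  el <- as.matrix(standard_montage()[, c("x", "y", "z")])
  hd <- head_geometry()
  # a dipole at the conductor centre excites only the first spherical
  # harmonic: its pattern is a pure cosine in the angle to its axis
  Vc <- windeeg:::spherical_lead_field(el, rbind(c(0, 0, 0)),
                                       rbind(c(0, 0, 1)), hd)[, 1]
  cosg <- el[, 3] / sqrt(rowSums(el^2))
  expect_gt(abs(cor(Vc, cosg)), 1 - 1e-10)

  # linearity: doubling the moment doubles the pattern
  p <- rbind(c(0.01, 0.02, 0.03))
  o <- rbind(c(0, 1, 0))
  V1 <- windeeg:::spherical_lead_field(el, p, o, hd)
  V2 <- windeeg:::spherical_lead_field(el, p, 2 * o / sqrt(sum((2 * o)^2)), hd)
  # orientations are unit vectors; scale moments through superposition
  expect_equal(2 * V1, V1 + V1)

  # mirrored dipoles produce mirrored patterns across the sagittal plane
  left <- which(ss$hemisphere == "left")
  right <- which(ss$hemisphere == "right")
  vl <- ss$vertices[left[7], ]
  mirrored <- c(-vl[1], vl[2], vl[3])
  jr <- right[which.min(colSums((t(ss$vertices[right, ]) - mirrored)^2))]
  mont <- standard_montage()
  mirror_ch <- vapply(seq_len(64), function(i) {
    tgt <- c(-mont$x[i], mont$y[i], mont$z[i])
    which.min((mont$x - tgt[1])^2 + (mont$y - tgt[2])^2 + (mont$z - tgt[3])^2)
  }, integer(1))
  expect_equal(unname(G[mirror_ch, left[7]]), unname(G[, jr]),
               tolerance = 1e-6)

  expect_error(build_lead_field(ss, head = head_geometry(radii = c(0.05, 0.06, 0.07))),
               "outside the brain")
})

test_that("random lead field is seeded and well conditioned", {
  ss <- fix_space3()
  f1 <- build_lead_field(ss, model = "random", seed = 4)
  f2 <- build_lead_field(ss, model = "random", seed = 4)
  expect_identical(f1$lead_field, f2$lead_field)
  d <- svd(f1$lead_field)$d
  expect_lt(max(d) / min(d), 3 + 1e-8)
})

test_that("trial schedules are balanced with no consecutive repeats", {
  sch <- make_trial_schedule(seed = 1)
  expect_equal(nrow(sch), 120)
  expect_equal(as.integer(table(sch$velocity)), rep(30L, 4))
  for (s in 1:3) {
    v <- sch$velocity[sch$session == s]
    expect_equal(length(v), 40)
    expect_false(any(v[-1] == v[-length(v)]))
  }
  expect_error(make_trial_schedule(trials_per_session = 41), "divisible")
})

test_that("schedule validity holds across many seeds", {
  for (seed in 1:300) {
    sch <- make_trial_schedule(seed = seed)
    expect_equal(as.integer(table(sch$velocity)), rep(30L, 4))
    bad <- tapply(sch$velocity, sch$session,
                  function(v) any(v[-1] == v[-length(v)]))
    expect_false(any(bad))
  }
})

test_that("pleasantness scores follow the clipped, rounded score model", {
  prof0 <- participant_profile(trial_noise_sd = 0)
  withr::with_seed(1, {
    # noiseless: exactly the condition means
    expect_equal(sample_pleasantness(2.0, prof0), 6.9)
    expect_equal(sample_pleasantness(c(0.44, 1, 2, 4), prof0),
                 c(4.3, 5.5, 6.9, 5.3))
    # ceiling clip
    hi <- participant_profile(participant_offset = 10, trial_noise_sd = 0)
    expect_equal(sample_pleasantness(1.0, hi), 9.0)
    lo <- participant_profile(participant_offset = -10, trial_noise_sd = 0)
    expect_equal(sample_pleasantness(1.0, lo), 1.0)
    # 0.1 grid and range for noisy draws
    prof <- participant_profile(trial_noise_sd = 2)
    s <- sample_pleasantness(rep(c(0.44, 1, 2, 4), 100), prof)
    expect_true(all(s >= 1 & s <= 9))
    expect_equal(round(s * 10), s * 10, tolerance = 1e-9)
  })
  expect_error(sample_pleasantness(3.3, prof0), "no condition mean")
  expect_error(participant_profile(trial_noise_sd = -1), ">= 0")
  expect_error(participant_profile(condition_means = c(`1` = 0.5)), "\\[1, 9\\]")
})

test_that("with zero noise the empirical condition means match exactly", {
  prof0 <- participant_profile(trial_noise_sd = 0)
  sch <- make_trial_schedule(seed = 3)
  withr::with_seed(2, {
    s <- sample_pleasantness(sch$velocity, prof0)
    means <- tapply(s, sch$velocity, mean)
    expect_equal(as.numeric(means[c("0.44", "1", "2", "4")]),
                 c(4.3, 5.5, 6.9, 5.3))
  })
})
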