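test_that("random_breaks: counts, dedup, seeding, mean spacing", {
  g <- circular_genome()
  expect_length(random_breaks(g, 0)$cut_positions, 0)
  b1 <- random_breaks(g, 100, rng_seed = 5)
  b2 <- random_breaks(g, 100, rng_seed = 5)
  expect_identical(b1, b2)
  expect_equal(b1$scenario, "random")
  expect_equal(b1$endedness, "two_ended")
  # mean inter-cut spacing ~ 50 kb at b = 100 on 5 Mb
  fr <- fragments_from_breaks(g, b1)
  expect_equal(mean(fr$arcs$length), 5e6 / length(b1$cut_positions))
  expect_error(random_breaks(g, -1), "non-negative")
})

test_that("random_breaks positions are uniform (KS, property)", {
  g <- circular_genome()
  bs <- random_breaks(g, 1e4, rng_seed = 123)
  ks <- suppressWarnings(
    stats::ks.test(bs$cut_positions / g$length_bp, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("shorter-arc fraction at b = 2 has mean 1/4 (Monte Carlo vs closed form)", {
  # analytic E[min(U, 1-U)] = 1/4 for the two-cut circle
  g <- circular_genome()
  set.seed(99)
  shorter <- vapply(seq_len(1e4), function(i) {
    fr <- fragments_from_breaks(g, random_breaks(g, 2))
    min(fr$arcs$length) / g$length_bp
  }, numeric(1))
  expect_equal(mean(shorter), 0.25, tolerance = 0.02)
})

test_that("scaffold_targeted_breaks cut distinct sites and destroy them", {
  g <- circular_genome()
  m <- build_attachment_map(g, 50, layout = "loop_rosette")
  bs <- scaffold_targeted_breaks(g, m, 10, rng_seed = 1)
  expect_length(bs$cut_positions, 10)
  expect_true(all(bs$cut_positions %in% m$scaffold_sites))
  post <- apply_breaks_to_map(m, bs)
  expect_length(post$scaffold_sites, 40)
  expect_false(any(bs$cut_positions %in% post$scaffold_sites))
  # over-requesting cuts all sites with a warning
  expect_warning(bs_all <- scaffold_targeted_breaks(g, m, 100, rng_seed = 1),
                 "cutting all")
  expect_length(bs_all$cut_positions, 50)
  expect_error(scaffold_targeted_breaks(
    g, build_attachment_map(g, 0, layout = "explicit"), 1),
    "no scaffold sites")
})

test_that("cutting all 50 loop bases releases every loop; n = 1 releases none", {
  g <- circular_genome()
  m <- build_attachment_map(g, 50, layout = "loop_rosette")
  bs <- suppressWarnings(scaffold_targeted_breaks(g, m, 50, rng_seed = 2))
  post <- apply_breaks_to_map(m, bs)
  fr <- fragments_from_breaks(g, bs, post)
  expect_equal(released_fraction(fr, post), 1)
  # a single scaffold cut opens the circle but 49 attachments remain
  bs1 <- scaffold_targeted_breaks(g, m, 1, rng_seed = 3)
  post1 <- apply_breaks_to_map(m, bs1)
  fr1 <- fragments_from_breaks(g, bs1, post1)
  expect_equal(nrow(fr1$arcs), 1)
  expect_equal(released_fraction(fr1, post1), 0)
})

test_that("rosette a=4 with envelope on 2 loops: cutting all bases frees 2 of 4 arcs", {
  g <- circular_genome(1000)
  m <- build_attachment_map(g, 4, 2, layout = "loop_rosette")
  bs <- scaffold_targeted_breaks(g, m, 4, rng_seed = 4)
  post <- apply_breaks_to_map(m, bs)
  fr <- fragments_from_breaks(g, bs, post)
  expect_equal(sum(!fr$arcs$envelope_attached & !fr$arcs$scaffold_attached), 2)
  expect_equal(released_fraction(fr, post), 0.5)
})

test_that("envelope_targeted_breaks release nothing on a rosette (property)", {
  g <- circular_genome()
  m <- build_attachment_map(g, 50, 50, layout = "loop_rosette")
  for (n in c(1, 10, 50)) {
    bs <- envelope_targeted_breaks(g, m, n, rng_seed = n)
    post <- apply_breaks_to_map(m, bs)
    fr <- fragments_from_breaks(g, bs, post)
    expect_identical(released_fraction(fr, post), 0)
    # every arc still contains a loop-base scaffold site
    expect_true(all(fr$arcs$scaffold_attached))
  }
  expect_error(envelope_targeted_breaks(
    g, build_attachment_map(g, 4, 0, layout = "loop_rosette"), 1),
    "no envelope sites")
})

test_that("rfc model: fork positions, breaks and species accounting", {
  g <- circular_genome()
  expect_error(rfc_state(0), "strictly in")
  expect_error(rfc_state(1.2), "strictly in")
  st <- rfc_state(0.3)
  expect_equal(unname(fork_positions(g, st)), c(0.75e6, 4.25e6))
  bs <- rfc_breaks(g, st)
  expect_equal(bs$endedness, "one_ended_rfc")
  expect_length(bs$cut_positions, 2)
  # both forks collapsed at progression 0.3: one ori-containing linear arm
  fr <- rfc_fragments(g, st)
  expect_equal(nrow(fr$arcs), 1)
  expect_equal(fr$arcs$length, 0.3 * 5e6)
  expect_true(fr$arcs$contains_ori)
  expect_false(fr$arcs$contains_ter)
  expect_true(fr$branched)
  expect_equal(fr$arcs$length + fr$residual_length, 5e6)
  # one fork collapsed at progression 0.5: arm length 0.5 * L (interval oracle)
  fr1 <- rfc_fragments(g, rfc_state(0.5, collapsed_forks = "cw"))
  expect_equal(fr1$arcs$length, 0.5 * 5e6)
  expect_equal(fr1$arcs$start, 5e6 - 1.25e6)
  expect_equal(fr1$arcs$end, 1.25e6)
  # no collapsed forks: intact theta, no smear species
  fr0 <- rfc_fragments(g, rfc_state(0.3, collapsed_forks = character(0)))
  expect_true(fr0$residual_circle)
  expect_equal(nrow(fr0$arcs), 0)
})
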