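test_that("criterion table satisfies the rubric invariants", {
  crit <- igapp_criteria()
  expect_equal(nrow(crit), 10)
  expect_equal(
    as.vector(table(factor(crit$section,
      levels = c("pre_processing", "printing", "post_curing")
    ))),
    c(4L, 4L, 2L)
  )
  expect_equal(sum(crit$weight), 10)
  expect_equal(crit$weight[crit$criterion == "energy"], 2)
  expect_equal(crit$weight[crit$section == "post_curing"], c(0.5, 0.5))
})

test_that("weighted totals reproduce the published profile sums", {
  # binder-jetting profile: sums to 7.25
  bj <- make_bands(
    n_actives = "red", print_time = "yellow", waste = "yellow",
    cure_process = "yellow", cure_time = "red"
  )
  expect_identical(igapp_total(bj), 7.25)

  # solvent-cast FDM profile: expected total derived by summing its ten
  # published sub-scores 0.5+0+0.5+0+0+0+0.5+1+0.5+0.5 = 3.5
  fdm2 <- make_bands(
    solvent_ei = "yellow", feed_temp = "red", solvent_removal = "yellow",
    n_actives = "red", energy = "red", print_temp = "red",
    print_time = "yellow"
  )
  expect_identical(igapp_total(fdm2), sum(published_points[["FDM 2"]]))

  expect_identical(igapp_total(make_bands(default = "green")), 10)
  expect_identical(igapp_total(make_bands(default = "red")), 0)
})

test_that("incomplete or malformed assignments are rejected by name", {
  bands <- make_bands()
  expect_error(igapp_total(bands[-3]), "missing criterion.*solvent_removal")
  expect_error(
    igapp_total(c(bands, solvent_ei = "red")),
    "duplicate criterion.*solvent_ei"
  )
  expect_error(
    igapp_total(c(bands[-1], bogus = "green")),
    "missing criterion.*solvent_ei|unknown criterion.*bogus"
  )
  bad <- bands
  bad["waste"] <- "purple"
  expect_error(igapp_total(bad), "invalid band")
  expect_error(igapp_total(unname(bands)), "named")
})

test_that("overall banding honours both threshold variants", {
  table2 <- igapp_rubric("table2")
  narrative <- igapp_rubric("narrative")
  expect_identical(overall_band(8, table2), "green")
  expect_identical(overall_band(4, table2), "red")
  expect_identical(overall_band(4, narrative), "red")
  # a 7.25 method is green under the narrative thresholds that reproduce
  # the published classifications, yellow under the tabulated ones
  expect_identical(overall_band(7.25, narrative), "green")
  expect_identical(overall_band(7.25, table2), "yellow")
  # boundary totals fall in the closed middle interval
  expect_identical(overall_band(5, narrative), "yellow")
  expect_identical(overall_band(5, table2), "yellow")
  expect_identical(overall_band(7, narrative), "yellow")
  expect_identical(overall_band(7.5, table2), "yellow")
  expect_error(overall_band(10.25), "\\[0, 10\\]")
  expect_error(overall_band(-0.5), "\\[0, 10\\]")
})

test_that("totals agree with a brute-force dot product over all 59049 assignments", {
  grid <- expand.grid(rep(list(c("green", "yellow", "red")), 10),
    stringsAsFactors = FALSE
  )
  names(grid) <- criteria_ids
  weights <- igapp_criteria()$weight
  frac <- c(green = 1, yellow = 0.5, red = 0)
  rubric <- igapp_rubric()
  mat <- as.matrix(grid)
  # independent oracle: floating-point dot product of weights and fractions
  oracle <- as.vector(matrix(frac[mat], nrow = nrow(mat)) %*% weights)
  got <- vapply(
    seq_len(nrow(mat)),
    function(i) igapp_total(stats::setNames(mat[i, ], criteria_ids), rubric),
    numeric(1)
  )
  expect_equal(got, oracle)
  expect_true(all(got >= 0 & got <= 10))
  # exact quarter-point granularity, no floating drift
  expect_identical(got * 4, round(got * 4))
})

test_that("upgrading one criterion raises the total by half its weight and never lowers the overall band", {
  rubric <- igapp_rubric()
  weights <- stats::setNames(igapp_criteria()$weight, criteria_ids)
  band_rank <- c(red = 0, yellow = 1, green = 2)
  set.seed(42)
  for (rep in 1:50) {
    bands <- stats::setNames(
      sample(c("green", "yellow", "red"), 10, replace = TRUE), criteria_ids
    )
    total <- igapp_total(bands, rubric)
    for (cr in criteria_ids) {
      if (bands[[cr]] == "green") next
      up <- bands
      up[[cr]] <- if (up[[cr]] == "red") "yellow" else "green"
      up_total <- igapp_total(up, rubric)
      expect_identical(up_total - total, weights[[cr]] / 2)
      expect_gte(
        band_rank[[overall_band(up_total, rubric)]],
        band_rank[[overall_band(total, rubric)]]
      )
    }
  }
})

test_that("score cards award weight-times-fraction points per criterion", {
  bands <- make_bands(
    energy = "yellow", cure_process = "yellow", waste = "red"
  )
  card <- igapp_score_card(bands, name = "probe")
  a <- card$assignments
  expect_identical(a$points, a$weight * unname(band_fraction(a$band)))
  expect_identical(card$total, sum(a$points))
  expect_identical(card$overall, overall_band(card$total))
  expect_identical(format_total(card$total), "7.75")
})

test_that("custom rubric weights are validated", {
  w <- stats::setNames(igapp_criteria()$weight, criteria_ids)
  expect_error(igapp_rubric(weights = w[-1]), "ten criteria")
  w_bad <- w
  w_bad["energy"] <- 2.3
  expect_error(igapp_rubric(weights = w_bad), "quarter-point")
  w_sum <- w
  w_sum["energy"] <- 3
  expect_error(igapp_rubric(weights = w_sum), "sum to 10")
})
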