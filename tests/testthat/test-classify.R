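test_that("feed-temperature bands break at 30 and 60 degC with a closed middle interval", {
  expect_identical(band_of(base_sse(feed_temperature = "ambient"), "feed_temp"), "green")
  expect_identical(band_of(base_sse(feed_temperature = 29), "feed_temp"), "green")
  expect_identical(band_of(base_sse(feed_temperature = 30), "feed_temp"), "yellow")
  expect_identical(band_of(base_sse(feed_temperature = 60), "feed_temp"), "yellow")
  expect_identical(band_of(base_sse(feed_temperature = 61), "feed_temp"), "red")
  # ranges classify by their maximum (worst case)
  expect_identical(band_of(base_sse(feed_temperature = c(20, 45)), "feed_temp"), "yellow")
})

test_that("printing-temperature bands treat up to 110 degC as moderate and above as red", {
  expect_identical(band_of(base_sse(print_temperature = "ambient"), "print_temp"), "green")
  expect_identical(band_of(base_sse(print_temperature = 25), "print_temp"), "green")
  expect_identical(band_of(base_sse(print_temperature = 26), "print_temp"), "yellow")
  expect_identical(band_of(base_sse(print_temperature = 110), "print_temp"), "yellow")
  expect_identical(band_of(base_sse(print_temperature = 111), "print_temp"), "red")
  expect_identical(band_of(base_sse(print_temperature = c(80, 100)), "print_temp"), "yellow")
})

test_that("printing-time bands break at 2.5 and 10 minutes", {
  expect_identical(band_of(base_sse(print_time = 2.4), "print_time"), "green")
  expect_identical(band_of(base_sse(print_time = 2.5), "print_time"), "yellow")
  expect_identical(band_of(base_sse(print_time = 10), "print_time"), "yellow")
  expect_identical(band_of(base_sse(print_time = 10.5), "print_time"), "red")
  expect_identical(band_of(base_sse(print_time = c(11, 14)), "print_time"), "red")
})

test_that("energy bands follow technology class and SSE pressure breaks at 100 and 500 kPa", {
  tech_band <- function(tech, ...) {
    band_of(base_sse(technology = tech, extrusion_pressure = NULL, ...), "energy")
  }
  expect_identical(tech_band("BJ"), "green")
  expect_identical(tech_band("SLA"), "yellow")
  expect_identical(tech_band("SLS"), "yellow")
  expect_identical(tech_band("FDM"), "red")
  expect_identical(band_of(base_sse(extrusion_pressure = 99), "energy"), "green")
  expect_identical(band_of(base_sse(extrusion_pressure = 100), "energy"), "yellow")
  expect_identical(band_of(base_sse(extrusion_pressure = 500), "energy"), "yellow")
  expect_identical(band_of(base_sse(extrusion_pressure = 501), "energy"), "red")
  expect_identical(band_of(base_sse(extrusion_pressure = c(55, 65)), "energy"), "green")
})

test_that("post-curing time bands break at one hour, with exactly 1 h still intermediate", {
  cure <- function(h) {
    band_of(base_sse(cure_process = "non_energy", cure_time = h), "cure_time")
  }
  expect_identical(band_of(base_sse(), "cure_time"), "green") # no post-curing
  expect_identical(cure(0.5), "yellow")
  expect_identical(cure(1), "yellow")
  expect_identical(cure(1.5), "red")
})

test_that("active-count, waste, removal and cure-process bands follow their categories", {
  expect_identical(band_of(base_sse(n_actives = 1), "n_actives"), "red")
  expect_identical(band_of(base_sse(n_actives = 2), "n_actives"), "yellow")
  expect_identical(band_of(base_sse(n_actives = 3), "n_actives"), "green")
  expect_identical(band_of(base_sse(waste = "none"), "waste"), "green")
  expect_identical(band_of(base_sse(waste = "recycled"), "waste"), "yellow")
  expect_identical(band_of(base_sse(waste = "disposed"), "waste"), "red")
  expect_identical(band_of(base_sse(solvent_removal = "none"), "solvent_removal"), "green")
  expect_identical(band_of(base_sse(solvent_removal = "evap_ambient"), "solvent_removal"), "yellow")
  expect_identical(band_of(base_sse(solvent_removal = "evap_heated"), "solvent_removal"), "red")
  cure_band <- function(p) {
    band_of(base_sse(cure_process = p, cure_time = if (p == "none") "none" else 0.5), "cure_process")
  }
  expect_identical(cure_band("none"), "green")
  expect_identical(cure_band("non_energy"), "green")
  expect_identical(cure_band("low_heat_drying"), "yellow")
  expect_identical(cure_band("high_energy"), "red")
})

test_that("solvent criterion resolves names through the registry and accepts explicit scores", {
  expect_identical(band_of(base_sse(), "solvent_ei"), "green") # solvent-free
  expect_identical(band_of(base_sse(feed_solvents = "water"), "solvent_ei"), "green")
  expect_identical(band_of(base_sse(feed_solvents = "propanol"), "solvent_ei"), "yellow")
  expect_identical(band_of(base_sse(feed_solvents = 3), "solvent_ei"), "red")
  expect_identical(
    band_of(base_sse(feed_solvents = list("water", 6)), "solvent_ei"), "yellow"
  )
  expect_error(
    classify_process(base_sse(feed_solvents = "unobtainium")),
    "not in the registry"
  )
})

test_that("each of the nine bundled profiles reproduces its published sub-scores and total", {
  fx <- igapp_fixtures()
  expect_length(fx, 9)
  for (nm in names(published_points)) {
    card <- igapp_score(fx[[nm]])
    expect_identical(card$assignments$points, published_points[[nm]],
      info = nm
    )
    expect_identical(card$total, sum(published_points[[nm]]), info = nm)
  }
})

test_that("classification is a pure, deterministic function of the description", {
  fx <- igapp_fixtures()$SLS
  expect_identical(classify_process(fx), classify_process(fx))
  expect_identical(igapp_pictogram(igapp_score(fx)), igapp_pictogram(igapp_score(fx)))
})

test_that("overrides replace the rule band last and stay visible in the audit trail", {
  sse <- igapp_fixtures()$SSE
  a <- classify_process(sse)
  row <- a[a$criterion == "cure_process", ]
  expect_identical(row$rule_band, "green") # ambient drying is non-energy
  expect_identical(row$band, "yellow") # published profile banded it yellow
  expect_true(row$overridden)
  expect_match(row$rationale, "override")
  # an override equal to the rule band is not flagged
  same <- base_sse(overrides = c(waste = "green"))
  expect_false(classify_process(same)$overridden[8])
  # rationale is always populated
  expect_true(all(nzchar(a$rationale)))
})

test_that("invalid process descriptions fail with messages naming the field", {
  expect_error(base_sse(extrusion_pressure = NULL), "extrusion_pressure")
  expect_error(
    base_sse(technology = "FDM"), # keeps the SSE pressure of 50
    "only to SSE"
  )
  expect_error(base_sse(n_actives = 0), "n_actives")
  expect_error(base_sse(n_actives = 1.5), "n_actives")
  expect_error(base_sse(print_time = -1), "print_time")
  expect_error(base_sse(feed_temperature = "hot"), "feed_temperature")
  expect_error(base_sse(cure_time = 2), "cure_process")
  expect_error(
    base_sse(cure_process = "non_energy", cure_time = "none"),
    "cure_time"
  )
  expect_error(base_sse(waste = "burned"), "'arg'")
  expect_error(base_sse(overrides = c(bogus = "green")), "criterion")
  expect_error(base_sse(overrides = c(waste = "purple")), "invalid override")
})
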