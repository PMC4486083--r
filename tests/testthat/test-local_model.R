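test_that("area weight is the consumption-weighted mean intake", {
  tab <- ssb_consumption()

  # an area of only 65+ men carries exactly that group's intake (15 kcal)
  only_old_men <- make_area("X1", ifelse(
    tab$gender == "male" & tab$age_band == "65+", 1000, 0))
  expect_equal(area_consumption_weight(only_old_men), 15)
  expect_equal(min(tab$kcal_low), 15)  # lowest-consuming group

  # uniform composition: plain mean of the kcal column
  uniform <- make_area("X2", rep(100, 8))
  expect_equal(area_consumption_weight(uniform), mean(tab$kcal_low))

  expect_error(area_consumption_weight(make_area("X3", rep(0, 8))),
               "all zero")
})

test_that("weight rises with the share of high-consuming age groups", {
  tab <- ssb_consumption()
  # brute-force oracle over a grid of compositions: moving head count from
  # 65+ into 11-18 must strictly increase the weight
  base_counts <- c(50, 50, 200, 100, 50, 50, 200, 100) * 10
  for (moved in c(10, 100, 500)) {
    shifted <- base_counts
    old_idx <- which(tab$age_band == "65+")
    teen_idx <- which(tab$age_band == "11-18")
    shifted[old_idx] <- shifted[old_idx] - moved / 2
    shifted[teen_idx] <- shifted[teen_idx] + moved / 2
    expect_gt(area_consumption_weight(make_area("A", shifted)),
              area_consumption_weight(make_area("A", base_counts)))
  }
})

test_that("disaggregation conserves national totals over arbitrary partitions", {
  nat <- toy_national(6.5)
  for (seed in 1:3) {
    pop <- generate_population(synth_config(
      n_areas = 40, total_adults = 500000, seed = seed))
    res <- disaggregate(nat, pop)
    expect_equal(sum(res$diabetes), nat$outcomes$annual_change[1],
                 tolerance = 1e-9)
    expect_equal(sum(res$qalys),
                 nat$outcomes$annual_change[nat$outcomes$outcome == "qalys"],
                 tolerance = 1e-9)
    expect_equal(sum(res$cost_savings), nat$cost_savings, tolerance = 1e-9)
    # per-person kcal across areas brackets the national value
    expect_lte(min(res$per_person_kcal), 6.5)
    expect_gte(max(res$per_person_kcal), 6.5)
  }
})

test_that("a single area or a symmetric split reproduces the national result", {
  nat <- toy_national(6.5)
  counts <- c(4, 5, 31, 9, 4, 5, 31, 11) * 1000
  one <- make_area("E92", counts, "All of England")
  res1 <- disaggregate(nat, one)
  expect_equal(res1$per_person_kcal, 6.5)
  expect_equal(res1$qalys,
               nat$outcomes$annual_change[nat$outcomes$outcome == "qalys"])

  # two demographically identical halves: per-person unchanged, totals split
  halves <- dplyr::bind_rows(make_area("H1", counts / 2),
                             make_area("H2", counts / 2))
  res2 <- disaggregate(nat, halves)
  expect_equal(res2$per_person_kcal, c(6.5, 6.5))
  expect_equal(res2$qalys[1], res2$qalys[2])
  expect_equal(sum(res2$qalys), res1$qalys)
  expect_equal(sum(res2$cost_savings), res1$cost_savings)
})

test_that("refinement with unequal sizes splits totals proportionally", {
  nat <- toy_national(5)
  counts <- c(4, 5, 31, 9, 4, 5, 31, 11) * 1000
  parts <- dplyr::bind_rows(make_area("P1", counts * 0.3),
                            make_area("P2", counts * 0.7))
  res <- disaggregate(nat, parts)
  expect_equal(res$per_person_kcal, c(5, 5))
  expect_equal(res$qalys[1] / res$qalys[2], 0.3 / 0.7)
})

test_that("malformed inputs are rejected", {
  nat <- toy_national()
  counts <- c(4, 5, 31, 9, 4, 5, 31, 11) * 100
  dup <- dplyr::bind_rows(make_area("D1", counts), make_area("D1", counts))
  expect_error(disaggregate(nat, dup), "duplicate")

  children_only <- make_area("C1", ifelse(
    ssb_consumption()$age_band %in% c("4-10", "11-18"), 100, 0))
  expect_error(disaggregate(nat, children_only), "no adult")
})

test_that("ranking sorts descending with area-code tie-breaks", {
  nat <- toy_national()
  counts <- c(4, 5, 31, 9, 4, 5, 31, 11) * 1000
  pop <- dplyr::bind_rows(make_area("B", counts * 2),
                          make_area("C", counts),
                          make_area("A", counts))
  ranked <- rank_areas(disaggregate(nat, pop), metric = "qalys")
  expect_equal(ranked$area_code, c("B", "A", "C"))  # A/C tie -> code order
  expect_equal(ranked$rank, 1:3)
  expect_true(all(diff(ranked$qalys) <= 0))
  expect_error(rank_areas(disaggregate(nat, pop), metric = "nope"),
               "unknown metric")
})

test_that("population CSV reader validates and round-trips", {
  counts <- c(4, 5, 31, 9, 4, 5, 31, 11) * 100
  pop <- make_area("R1", counts)
  path <- withr::local_tempfile(fileext = ".csv")
  write_area_populations(pop, path)
  back <- read_area_populations(path)
  expect_equal(as.data.frame(back), as.data.frame(pop))

  bad <- pop
  bad$age_band[3] <- "12-17"
  write_area_populations(bad, path)
  expect_error(read_area_populations(path), "'12-17' at line 4")
})
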