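test_that("species table round trip preserves all fields and validates vocab", {
  for (seed in 1:3) {
    df <- random_species_table(20, seed = seed)
    path <- withr::local_tempfile(fileext = ".csv")
    write_species_table(df, path)
    back <- read_species_table(path)
    expect_equal(back$species_id, df$species_id)
    expect_equal(back$body_mass, df$body_mass, tolerance = 1e-12)
    expect_identical(back$habitat, df$habitat)
    expect_identical(back$migration, df$migration)
    expect_identical(back$native, df$native)
  }
})

test_that("species table validation is row-addressed", {
  df <- random_species_table(5)
  df$body_mass[3] <- -1
  expect_error(validate_species_table(df), "row 3")
  df <- random_species_table(5)
  df$habitat[2] <- "tundra"
  expect_error(validate_species_table(df), "unknown habitat.*row 2")
  df <- random_species_table(5)
  df$migration[4] <- "nomadic"
  expect_error(validate_species_table(df), "row 4")
  df <- random_species_table(5)
  df$species_id[2] <- df$species_id[1]
  expect_error(validate_species_table(df), "duplicate")
  expect_error(validate_species_table(random_species_table(3)[, -2]),
               "missing required column")
})

test_that("index series reader validates and orders rows", {
  df <- data.frame(species_id = c("b", "a", "a"), year = c(2000, 2001, 2000),
                   index = c(1, 2, 3), se = c(0.1, 0.2, 0.3))
  out <- validate_index_series(df)
  expect_equal(out$species_id, c("a", "a", "b"))
  expect_equal(out$year, c(2000, 2001, 2000))
  df$index[1] <- -1
  expect_error(validate_index_series(df), "index must be >= 0")
  df2 <- data.frame(species_id = "a", year = c(2000, 2000), index = 1,
                    se = 0.1)
  expect_error(validate_index_series(df2), "duplicate")
  df3 <- data.frame(species_id = "a", year = 2000:2001, index = 1,
                    se = 0.1, coverage = c(0.5, 1.2))
  expect_error(validate_index_series(df3), "coverage")
})

test_that("population estimates derive point and se when absent", {
  df <- data.frame(species_id = c("a", "b"), min_est = c(60, 500),
                   max_est = c(120, 500), ref_year_start = 2016,
                   ref_year_end = 2016)
  out <- validate_population_estimates(df)
  expect_equal(out$point, c(sqrt(60 * 120), 500))
  expect_equal(out$se, c(10, 0))
  df$min_est[1] <- 200
  expect_error(validate_population_estimates(df), "min_est <= max_est")
})

test_that("tabular round trips hold for estimates and national trends", {
  set.seed(9)
  est <- data.frame(species_id = sprintf("s%02d", 1:10),
                    min_est = exp(runif(10, 3, 10)))
  est$max_est <- est$min_est * runif(10, 1, 3)
  est$ref_year_start <- 2013L
  est$ref_year_end <- 2017L
  est <- validate_population_estimates(est)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_population_estimates(est, p1)
  expect_equal(read_population_estimates(p1), est, tolerance = 1e-12)

  nt <- data.frame(species_id = "s01", country = c("AT", "BE", "CZ"),
                   mean_trend = c(1.2, 0.8, 1.0), trend_period = c(10, 12, 8),
                   mean_pop = c(1e4, 2e4, 5e3),
                   mean_estimate_year = c(2008, 2010, 2009))
  nt <- validate_national_trends(nt)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_national_trends(nt, p2)
  expect_equal(read_national_trends(p2), nt, tolerance = 1e-12)
  bad <- nt; bad$mean_trend[2] <- -0.1
  expect_error(validate_national_trends(bad), "mean_trend")
})

test_that("newick reader exposes tips and depths for a known tree", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", path)
  tree <- read_phylogeny(path)
  expect_setequal(tree$tip.label, c("A", "B", "C"))
  depths <- diag(ape::vcv(tree))
  expect_equal(unname(depths[c("A", "B", "C")]), c(2, 2, 2))
  md <- match_tree_species(tree, c("A", "B", "D"))
  expect_identical(md$only_tree, "C")
  expect_identical(md$only_table, "D")
})

test_that("newick round trip preserves a 50-tip Yule tree to 1e-9", {
  set.seed(4)
  tree <- ape::rphylo(50, birth = 0.1, death = 0)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_phylogeny(tree, path)
  back <- read_phylogeny(path)
  expect_identical(sort(back$tip.label), sort(tree$tip.label))
  ## same pairwise distances => same topology and lengths
  d0 <- ape::cophenetic.phylo(tree)
  d1 <- ape::cophenetic.phylo(back)[rownames(d0), colnames(d0)]
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("newick reader rejects duplicates and unparseable input", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,A:1):1,C:2);", path)
  expect_error(read_phylogeny(path), "duplicate")
  writeLines("not a tree at all", path)
  suppressWarnings(expect_error(read_phylogeny(path)))
})

test_that("analysis config round trips through YAML", {
  cfg <- analysis_config(1966, 2018, bootstrap_n = 500,
                         exclude_species = c("tawny_pipit", "crested_lark"))
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(year_start = 1966, year_end = 2018,
                        bootstrap_n = 500,
                        exclude_species = c("tawny_pipit", "crested_lark")),
                   path)
  cfg2 <- read_analysis_config(path)
  expect_equal(cfg2$year_start, cfg$year_start)
  expect_equal(cfg2$bootstrap_n, 500)
  expect_identical(cfg2$exclude_species, cfg$exclude_species)
  expect_error(analysis_config(2020, 2019), "year_start < year_end")
})
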