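test_that("make_scenario is seed-reproducible and shows redox zonation", {
  a <- make_scenario(seed = 6)
  b <- make_scenario(seed = 6)
  expect_identical(a$truth$k, b$truth$k)
  expect_identical(a$result$conc, b$result$conc)
  # truth inside the declared bounds
  for (i in seq_along(a$truth$specs)) {
    s <- a$truth$specs[[i]]
    expect_gte(a$truth$k[[i]], s$lower)
    expect_lte(a$truth$k[[i]], s$upper)
  }
  # qualitative redox zonation at the end of the season: oxygen maximal at
  # the surface, reduced species maximal at depth
  last <- dim(a$result$conc)[3]
  top_third <- 1:8; bottom_third <- 16:23
  expect_identical(which.max(a$result$conc["O2", , last]), 1L)
  for (sp in c("Fe2", "HS", "CH4")) {
    expect_gt(mean(a$result$conc[sp, bottom_third, last]),
              mean(a$result$conc[sp, top_third, last]))
  }
})

test_that("with all rate constants zero the chemistry is pure transport", {
  syn0 <- make_scenario(seed = 2, n_free_params = 0, free_processes = character(0))
  net0 <- knockout(syn0$network, process_labels(syn0$network))
  st <- default_scenario_settings()
  init <- model_state(st$grid, net0, st$initial_profiles)
  res <- integrate_lake(st$grid, net0, init, 30, 10)
  expect_true(all(res$rates == 0))
  # on a closed grid (no boundary sources) every element is conserved
  closed <- lake_grid()
  res2 <- integrate_lake(closed, net0,
                         model_state(closed, net0, st$initial_profiles), 30, 10)
  led <- res2$ledger
  for (e in c("Fe", "S", "N", "C")) {
    expect_lt(max(abs(led[[e]] - led[[e]][1])) / led[[e]][1], 1e-5)
  }
})

test_that("make_observations: zero noise is exact, noise is mean-preserving", {
  syn <- make_scenario(seed = 3, n_free_params = 0, free_processes = character(0))
  res <- syn$result
  obs0 <- make_observations(res, noise_sd = 0, seed = 1)
  one <- obs0[obs0$observable == "O2" & obs0$time_day == 140, ]
  ti <- which.min(abs(res$times - 140))
  expect_equal(one$value,
               approx(res$grid$depths, res$conc["O2", , ti],
                      xout = one$depth_m, rule = 2)$y)
  expect_true(all(obs0$value >= 0))
  # seeded reproducibility
  expect_identical(make_observations(res, noise_sd = 0.2, seed = 9),
                   make_observations(res, noise_sd = 0.2, seed = 9))
  # lognormal noise with sigma^2/2 offset preserves the mean
  set.seed(1)
  draws <- replicate(1000, {
    o <- make_observations(res, depths = 11, times = 140, noise_sd = 0.3,
                           seed = sample.int(1e6, 1), observables = "SO4")
    o$value
  })
  truth <- make_observations(res, depths = 11, times = 140, noise_sd = 0,
                             observables = "SO4")$value
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - truth), 3 * se)
})

test_that("make_gene_tables closes the loop with modeled_gene_proxy", {
  syn <- make_scenario(seed = 3, n_free_params = 0, free_processes = character(0))
  res <- syn$result
  genes0 <- suppressWarnings(make_gene_tables(res, noise_sd = 0, seed = 1))
  gpm <- default_gene_process_map()
  for (gs in names(gpm)) {
    proxy <- suppressWarnings(
      modeled_gene_proxy(res, gpm, gs, genes0[[gs]]$sample_depths,
                         attr(genes0[[gs]], "sample_time")))
    expect_identical(mae(genes0[[gs]], proxy), 0)
  }
  # dsrAB table reflects the summed sulfate-reduction + sulfide-oxidation rates
  fld <- process_rate_profile(res, c("sulfate_reduction", "sulfide_ox_o2",
                                     "sulfide_ox_no3"))
  ti <- which.min(abs(res$times - max(res$times)))
  v <- approx(res$grid$depths, fld[, ti], xout = genes0$dsrAB$sample_depths,
              rule = 2)$y
  expect_equal(genes0$dsrAB$values, v / sum(v))
  # noise monotonicity: expected MAE against the noise-free proxy grows
  mae_at <- function(sd) {
    mean(vapply(1:100, function(i) {
      g <- suppressWarnings(make_gene_tables(res, noise_sd = sd, seed = i))
      mae(g$dsrAB$values, genes0$dsrAB$values)
    }, numeric(1)))
  }
  m_small <- mae_at(0.05); m_mid <- mae_at(0.2); m_big <- mae_at(0.5)
  expect_lt(m_small, m_mid)
  expect_lt(m_mid, m_big)
})

test_that("make_community output is reproducible and structurally sound", {
  c1 <- make_community(seed = 12)
  c2 <- make_community(seed = 12)
  expect_identical(c1, c2)
  expect_identical(dim(c1$amplicon), c(62L, 11L))
  expect_identical(dim(c1$metagenomic), c(62L, 11L))
  expect_true(all(c1$amplicon >= 0))
  expect_identical(sum(c1$planted$control), 8L)
  # every planted MAG has 3-10 contigs with positive lengths
  tab <- table(c1$contigs$bin_id)
  expect_true(all(tab >= 3 & tab <= 10))
  expect_true(all(c1$contigs$length_bp > 0))
  # worst taxonomic matches are confined to the control set
  expect_true(all(c1$planted$match_depth[!c1$planted$control] >= 5))
  expect_true(any(c1$planted$match_depth[c1$planted$control] == 4))
})

test_that("noise-free community gives perfect separation of planted pairs", {
  comm <- make_community(seed = 21, noise_sd = 0)
  res <- suppressWarnings(run_matching(comm))
  # multinomial sampling noise remains, but every planted pair must be
  # recovered and no partner-less OTU accepted
  expect_identical(res$recovery, 1)
  expect_identical(res$false_acceptance, 0)
  # planted pairs' combined metric is at most -match_depth/6 + small noise
  pk <- paste(comm$planted$otu_id, comm$planted$mag_id)
  mm <- res$matches
  planted_m <- mm$m_amplicon[paste(mm$otu_id, mm$mag_id) %in% pk]
  expect_true(all(planted_m < -0.5))
})

test_that("generated tables pass the input validators", {
  comm <- make_community(seed = 33)
  dir <- withr::local_tempdir()
  otu_path <- file.path(dir, "otu.tsv")
  utils::write.table(data.frame(otu_id = rownames(comm$amplicon),
                                comm$amplicon, check.names = FALSE),
                     otu_path, sep = "\t", row.names = FALSE, quote = FALSE)
  contig_path <- file.path(dir, "contigs.tsv")
  utils::write.table(comm$contigs, contig_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  rep <- validate_inputs(list(otu_table = otu_path, contigs = contig_path))
  expect_true(rep$ok)
})
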