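test_that("bin_abundance implements the length-weighted coverage mean", {
  expect_identical(bin_abundance(1000, 7), 7)
  expect_equal(bin_abundance(c(1000, 3000), c(10, 2)), 4.0)
  expect_identical(bin_abundance(c(500, 500), c(0, 0)), 0)
  expect_equal(bin_abundance(c(1000, 3000), c(10, 2), library_reads = 1e6),
               4e-6)
  expect_error(bin_abundance(c(0, 10), c(1, 1)), "positive")
  # invariance to splitting a contig into two equal-coverage halves
  expect_equal(bin_abundance(c(2000, 500), c(3, 8)),
               bin_abundance(c(1000, 1000, 500), c(3, 3, 8)))
})

test_that("dual_l1_normalize runs columns first then rows", {
  m <- matrix(c(2, 2, 0, 4), nrow = 2)
  out <- dual_l1_normalize(m)
  expect_equal(unname(out), matrix(c(1, 1/3, 0, 2/3), nrow = 2),
               ignore_attr = TRUE)
  expect_identical(attr(out, "normalization_state"), "dual_l1")
  # nonzero rows sum to one
  expect_equal(unname(rowSums(out)), c(1, 1))
  # equal-valued matrix: uniform rows
  u <- dual_l1_normalize(matrix(5, 3, 4))
  expect_equal(unname(u), matrix(0.25, 3, 4), ignore_attr = TRUE)
  # row step is idempotent
  again <- sweep(out, 1, rowSums(out), "/")
  expect_equal(unname(again), unname(out), ignore_attr = TRUE)
  expect_warning(dual_l1_normalize(matrix(c(0, 0, 1, 2), nrow = 2)), "zero")
})

test_that("taxonomy_fraction counts independent level matches over MAG ranks", {
  a <- c("Bacteria", "Proteobacteria", "Beta", "Ord", "Fam", "Gen")
  expect_identical(taxonomy_fraction(a, a), 1)
  otu <- c("Bacteria", "Proteobacteria", "Gamma")
  mag <- c("Bacteria", "Proteobacteria", "Beta")
  expect_equal(taxonomy_fraction(otu, mag), 2 / 3)
  expect_identical(taxonomy_fraction(c("Archaea"), c("Bacteria")), 0)
  # a shallow mismatch does not invalidate deeper matches
  deep <- c("Archaea", "Proteobacteria", "Beta")
  expect_equal(taxonomy_fraction(deep, mag), 2 / 3)
  # unassigned MAG ranks shrink the denominator
  mag_partial <- c("Bacteria", "Proteobacteria", NA, NA, NA, NA)
  expect_identical(taxonomy_fraction(a, mag_partial), 1)
  expect_error(taxonomy_fraction(a, rep(NA_character_, 6)), "no assigned")
})

test_that("combined_distance endpoints and bounds", {
  row <- c(0.2, 0.5, 0.3)
  expect_identical(combined_distance(row, row, 1), -1)
  expect_identical(combined_distance(row, row, 0), 0)
  expect_equal(combined_distance(c(1, 0), c(0, 1), 1), sqrt(2) - 1)
  expect_error(combined_distance(c(1, 0), c(1, 0, 0), 0.5), "lengths")
  # m >= -1 with equality only for identical rows and f = 1
  set.seed(31)
  for (i in 1:50) {
    n <- sample(2:11, 1)
    a <- runif(n); a <- a / sum(a)
    b <- runif(n); b <- b / sum(b)
    f <- runif(1)
    m <- combined_distance(a, b, f)
    expect_gte(m, -1)
    if (m == -1) {
      expect_identical(a, b)
      expect_identical(f, 1)
    }
  }
})

test_that("train_tolerance is the max combined distance over controls", {
  expect_identical(train_tolerance(-0.2), -0.2)
  expect_identical(train_tolerance(c(-0.5, -0.2, 0.1)), 0.1)
  expect_error(train_tolerance(numeric(0)), "no control")
})

test_that("filter_taxonomy removes low-confidence and Incertae Sedis ranks independently", {
  nm <- matrix(c("Bacteria", "Proteobacteria", "Beta", "Ord", "Fam", "Gen"),
               nrow = 1)
  cf <- matrix(c(100, 99, 80, 70, 60, 40), nrow = 1)
  out <- filter_taxonomy(nm, cf)
  expect_identical(out[1, 6], NA_character_)  # genus below 50
  expect_identical(out[1, 1:5], nm[1, 1:5])   # everything else kept
  nm2 <- nm; nm2[1, 5] <- "Incertae Sedis XI"; cf2 <- cf; cf2[1, 5] <- 99
  out2 <- filter_taxonomy(nm2, cf2)
  expect_identical(out2[1, 5], NA_character_)  # name rule beats confidence
  expect_identical(out2[1, 4], "Ord")          # deeper/shallower independent
  all_good <- filter_taxonomy(nm, matrix(rep(90, 6), nrow = 1))
  expect_identical(all_good, nm)
})

test_that("match_otus_mags applies the both-datasets rule and one-to-one greedy", {
  samples <- paste0("s", 1:4)
  rowsA <- rbind(o1 = c(0.7, 0.2, 0.05, 0.05), o2 = c(0.05, 0.05, 0.2, 0.7))
  colnames(rowsA) <- samples
  mags <- rbind(b1 = c(0.7, 0.2, 0.05, 0.05), b2 = c(0.05, 0.05, 0.2, 0.7))
  colnames(mags) <- samples
  tax <- list(o1 = c("Bacteria", "P1"), o2 = c("Bacteria", "P2"),
              b1 = c("Bacteria", "P1"), b2 = c("Bacteria", "P2"))
  # o2 matches b2 in the amplicon data but is ruined in the metagenomic data
  rowsB <- rowsA
  rowsB["o2", ] <- c(0.9, 0.1, 0, 0)
  res <- match_otus_mags(rowsA, rowsB, mags, tax[1:2], tax[3:4],
                         tol_amplicon = -0.5, tol_metagenomic = -0.5)
  acc <- res[res$accepted, ]
  expect_identical(acc$otu_id, "o1")
  expect_identical(acc$mag_id, "b1")
  # conjunction rule: o2-b2 passes amplicon but fails metagenomic
  o2b2 <- res[res$otu_id == "o2" & res$mag_id == "b2", ]
  expect_true(o2b2$m_amplicon <= -0.5 && o2b2$m_metagenomic > -0.5)
  expect_false(o2b2$accepted)
  expect_error(
    match_otus_mags(rowsA, rowsB, mags[, c(1, 2), drop = FALSE][, 0],
                    tax[1:2], tax[3:4], 0, 0),
    "share no samples"
  )
})

test_that("gene-content clustering follows Spearman complete linkage", {
  prof <- rbind(
    A = c(1, 2, 3, 4, 5),
    B = c(10, 20, 30, 40, 50),    # monotone transform of A: rho = 1
    C = c(5, 4, 3, 2, 1)          # reversed: rho = -1
  )
  hc <- cluster_gene_content(prof)
  # A and B merge first at height 0, C joins at 1 - (-1) = 2
  expect_equal(hc$height, c(0, 2))
  first <- rownames(prof)[-hc$merge[1, ]]
  expect_setequal(first, c("A", "B"))
  expect_error(cluster_gene_content(rbind(A = c(1, 1, 1), B = c(1, 2, 3))),
               "constant")
})

test_that("matching output is invariant to feature relabeling", {
  comm <- make_community(seed = 5)
  r1 <- suppressWarnings(run_matching(comm))
  # relabel OTUs in reverse order everywhere
  comm2 <- comm
  relab <- function(ids) paste0("zz_", ids)
  rownames(comm2$amplicon) <- relab(rownames(comm$amplicon))
  rownames(comm2$metagenomic) <- relab(rownames(comm$metagenomic))
  names(comm2$otu_taxonomy) <- relab(names(comm$otu_taxonomy))
  comm2$planted$otu_id <- relab(comm$planted$otu_id)
  r2 <- suppressWarnings(run_matching(comm2))
  expect_identical(r1$recovery, r2$recovery)
  a1 <- r1$matches[r1$matches$accepted, ]
  a2 <- r2$matches[r2$matches$accepted, ]
  expect_identical(relab(a1$otu_id), a2$otu_id[match(a1$mag_id, a2$mag_id)])
})
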