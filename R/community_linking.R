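#' Coverage-weighted bin abundance
#'
#' Raw abundance of a metagenomic bin in sample j: the length-weighted mean
#' coverage of its contigs,
#' \deqn{A_j = \frac{\sum_i l_i c_{ij}}{\sum_i l_i}}
#' optionally divided by the library read count.
#'
#' @param lengths Contig lengths in bp (> 0).
#' @param coverages Per-contig mean coverage in sample j (>= 0), same length.
#' @param library_reads Optional read count of the library; when given, the
#'   raw value is divided by it.
#' @return Scalar abundance.
#' @export
bin_abundance <- function(lengths, coverages, library_reads = NULL) {
  stopifnot(length(lengths) >= 1L, length(coverages) == length(lengths))
  if (any(lengths <= 0)) stop("contig lengths must be positive")
  if (any(coverages < 0)) stop("coverages must be nonnegative")
  tot <- sum(lengths)
  if (tot == 0) stop("zero total contig length")
  a <- sum(lengths * coverages) / tot
  if (!is.null(library_reads)) {
    stopifnot(library_reads > 0)
    a <- a / library_reads
  }
  a
}

#' Bin abundance matrix from contig records
#'
#' @param contigs Data frame with columns `contig_id`, `bin_id`, `length_bp`,
#'   plus one numeric coverage column per sample.
#' @param library_reads Named vector of per-sample library read counts, or
#'   `NULL` to skip the division.
#' @return bins x samples numeric matrix (raw, un-normalized).
#' @export
bin_abundance_matrix <- function(contigs, library_reads = NULL) {
  meta <- c("contig_id", "bin_id", "length_bp")
  stopifnot(all(meta %in% names(contigs)))
  samples <- setdiff(names(contigs), meta)
  bins <- sort(unique(contigs$bin_id))
  A <- matrix(0, nrow = length(bins), ncol = length(samples),
              dimnames = list(bins, samples))
  for (b in bins) {
    sub <- contigs[contigs$bin_id == b, ]
    for (s in samples) {
      A[b, s] <- bin_abundance(sub$length_bp, sub[[s]],
                               if (is.null(library_reads)) NULL else library_reads[[s]])
    }
  }
  A
}

#' Dual-axis L1 normalization
#'
#' Normalizes an abundance matrix (features x samples) within samples first
#' (each column divided by its sum) and then within features (each row
#' divided by its sum). Zero columns/rows are left at zero with a warning.
#'
#' @param mat Nonnegative numeric matrix, features x samples.
#' @return Matrix of the same shape; every nonzero row sums to 1. The
#'   attribute `normalization_state` is set to `"dual_l1"`.
#' @export
dual_l1_normalize <- function(mat) {
  stopifnot(is.matrix(mat), all(mat >= 0))
  cs <- colSums(mat)
  if (any(cs == 0)) warning("zero sample column(s) left at zero")
  cs[cs == 0] <- 1
  mat <- sweep(mat, 2, cs, "/")
  rs <- rowSums(mat)
  if (any(rs == 0)) warning("zero feature row(s) left at zero")
  rs[rs == 0] <- 1
  mat <- sweep(mat, 1, rs, "/")
  attr(mat, "normalization_state") <- "dual_l1"
  mat
}

#' Fraction of matching taxonomy levels
#'
#' Levels (kingdom to genus) are compared independently: a mismatch at a
#' shallow rank does not invalidate a deeper match. The denominator is the
#' number of assigned ranks in the MAG taxonomy.
#'
#' @param otu_tax,mag_tax Character vectors of up to 6 rank names, `NA` for
#'   unassigned, aligned by rank position (1 = kingdom ... 6 = genus).
#' @return Fraction in \[0, 1\].
#' @export
taxonomy_fraction <- function(otu_tax, mag_tax) {
  n <- max(length(otu_tax), length(mag_tax))
  otu_tax <- c(otu_tax, rep(NA_character_, n - length(otu_tax)))
  mag_tax <- c(mag_tax, rep(NA_character_, n - length(mag_tax)))
  assigned <- !is.na(mag_tax)
  if (!any(assigned)) stop("MAG taxonomy has no assigned ranks")
  hits <- assigned & !is.na(otu_tax) & otu_tax == mag_tax
  sum(hits) / sum(assigned)
}

#' Combined OTU-to-MAG distance
#'
#' Euclidean distance between the dual-L1-normalized abundance rows minus
#' the taxonomy match fraction: m = ||otu - mag||_2 - f. A perfect match
#' (identical rows, fully matching taxonomy) scores -1, the metric's lower
#' bound.
#'
#' @param otu_row,mag_row Equal-length abundance rows (dual-L1 normalized).
#' @param f Taxonomy match fraction in \[0, 1\].
#' @return Combined metric m >= -1.
#' @export
combined_distance <- function(otu_row, mag_row, f) {
  if (length(otu_row) != length(mag_row)) {
    stop("abundance rows have different lengths")
  }
  stopifnot(f >= 0, f <= 1)
  sqrt(sum((otu_row - mag_row)^2)) - f
}

#' Train the acceptance tolerance on control pairs
#'
#' The tolerance is the smallest threshold admitting every known-correct
#' control pair, i.e. the maximum of their combined distances.
#'
#' @param control_m Numeric vector of combined distances of control pairs.
#' @return Scalar tolerance.
#' @export
train_tolerance <- function(control_m) {
  if (length(control_m) == 0L) stop("no control pairs supplied")
  max(control_m)
}

#' Filter an RDP-style fixed-rank taxonomy
#'
#' Ranks with confidence below `min_conf` percent or whose name contains
#' "Incertae Sedis" are set to unassigned. Levels are independent: a rank is
#' kept whenever its own confidence passes, regardless of shallower ranks.
#'
#' @param names_mat Character matrix (features x ranks) of rank names.
#' @param conf_mat Numeric matrix of confidences (0-100), same shape.
#' @param min_conf Confidence threshold (default 50).
#' @return Character matrix with failing ranks set to `NA`.
#' @export
filter_taxonomy <- function(names_mat, conf_mat, min_conf = 50) {
  stopifnot(identical(dim(names_mat), dim(conf_mat)))
  drop <- conf_mat < min_conf | grepl("Incertae Sedis", names_mat, fixed = TRUE)
  names_mat[drop | is.na(names_mat)] <- NA_character_
  names_mat
}

#' Read an RDP fixed-rank taxonomy TSV
#'
#' Dialect: `feature_id`, then `<rank>_name` / `<rank>_conf` column pairs for
#' kingdom, phylum, class, order, family, genus.
#'
#' @param path TSV file.
#' @param min_conf Confidence threshold applied via [filter_taxonomy()];
#'   `NULL` to skip filtering.
#' @return Named list of character rank vectors (NA = unassigned).
#' @export
read_taxonomy <- function(path, min_conf = 50) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  nm <- as.matrix(df[, paste0(ranks, "_name")])
  cf <- as.matrix(df[, paste0(ranks, "_conf")])
  if (!is.null(min_conf)) nm <- filter_taxonomy(nm, cf, min_conf)
  out <- lapply(seq_len(nrow(nm)), function(i) unname(nm[i, ]))
  names(out) <- df$feature_id
  out
}

.pairwise_combined <- function(otus, mags, otu_tax, mag_tax) {
  pairs <- expand.grid(otu_id = rownames(otus), mag_id = rownames(mags),
                       stringsAsFactors = FALSE)
  pairs$d <- NA_real_
  pairs$f <- NA_real_
  for (i in seq_len(nrow(pairs))) {
    o <- pairs$otu_id[i]; b <- pairs$mag_id[i]
    pairs$d[i] <- sqrt(sum((otus[o, ] - mags[b, ])^2))
    pairs$f[i] <- taxonomy_fraction(otu_tax[[o]], mag_tax[[b]])
  }
  pairs$m <- pairs$d - pairs$f
  pairs
}

#' Match OTUs to MAGs across two datasets
#'
#' Computes the combined metric for every OTU x MAG pair in the amplicon and
#' in the metagenomic dataset (matrices must already be dual-L1 normalized
#' on the shared sample set); a pair is acceptable only if its metric is
#' within the trained tolerance in *both* datasets. Acceptable pairs are
#' assigned one-to-one greedily by ascending amplicon metric (ties broken by
#' lexicographic otu_id, then mag_id) unless `many_to_one = TRUE`.
#'
#' @param otu_amplicon,otu_metagenomic OTU abundance matrices (rows = OTUs,
#'   the same ids in both), dual-L1 normalized.
#' @param mags MAG abundance matrix, dual-L1 normalized, same sample columns.
#' @param otu_taxonomy,mag_taxonomy Named lists of rank vectors.
#' @param tol_amplicon,tol_metagenomic Trained tolerances per dataset.
#' @param many_to_one Allow several OTUs per MAG (default `FALSE`).
#' @return Data frame of candidates: `otu_id`, `mag_id`, `d_amplicon`,
#'   `d_metagenomic`, `f`, `m_amplicon`, `m_metagenomic`, `accepted`.
#' @export
match_otus_mags <- function(otu_amplicon, otu_metagenomic, mags,
                            otu_taxonomy, mag_taxonomy,
                            tol_amplicon, tol_metagenomic,
                            many_to_one = FALSE) {
  shared <- intersect(colnames(otu_amplicon), colnames(mags))
  if (length(shared) == 0L) stop("OTU and MAG tables share no samples")
  if (!setequal(colnames(otu_amplicon), colnames(mags)) ||
      !setequal(colnames(otu_metagenomic), colnames(mags))) {
    stop("matrices must be restricted to the shared sample set before normalization")
  }
  mags <- mags[, colnames(otu_amplicon), drop = FALSE]
  otu_metagenomic <- otu_metagenomic[rownames(otu_amplicon),
                                     colnames(otu_amplicon), drop = FALSE]

  pa <- .pairwise_combined(otu_amplicon, mags, otu_taxonomy, mag_taxonomy)
  pm <- .pairwise_combined(otu_metagenomic, mags, otu_taxonomy, mag_taxonomy)
  cand <- data.frame(
    otu_id = pa$otu_id, mag_id = pa$mag_id,
    d_amplicon = pa$d, d_metagenomic = pm$d, f = pa$f,
    m_amplicon = pa$m, m_metagenomic = pm$m,
    stringsAsFactors = FALSE
  )
  cand$passes <- cand$m_amplicon <= tol_amplicon &
    cand$m_metagenomic <= tol_metagenomic
  cand$accepted <- FALSE

  ord <- order(cand$m_amplicon, cand$otu_id, cand$mag_id)
  used_otu <- character(0)
  used_mag <- character(0)
  for (i in ord) {
    if (!cand$passes[i]) next
    if (cand$otu_id[i] %in% used_otu) next
    if (!many_to_one && cand$mag_id[i] %in% used_mag) next
    cand$accepted[i] <- TRUE
    used_otu <- c(used_otu, cand$otu_id[i])
    used_mag <- c(used_mag, cand$mag_id[i])
  }
  cand
}

#' Gene-content clustering of features
#'
#' Complete-linkage agglomerative clustering with the Spearman rank
#' correlation distance 1 - rho between gene-content profiles.
#'
#' @param profiles Numeric matrix, features x genes; every row needs at
#'   least two distinct values for ranks to be defined.
#' @return An `hclust` merge tree.
#' @export
cluster_gene_content <- function(profiles) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 2L)
  const <- apply(profiles, 1, function(r) length(unique(r)) < 2L)
  if (any(const)) {
    stop("constant gene-content profile(s): ",
         paste(rownames(profiles)[const], collapse = ", "))
  }
  rho <- stats::cor(t(profiles), method = "spearman")
  d <- stats::as.dist(1 - rho)
  stats::hclust(d, method = "complete")
}
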