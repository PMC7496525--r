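# Haplotype clustering, dosage groups and additive phenotype regression.
#
# Phased cohort haplotypes over the locus's variant sites are clustered
# into two groups (A = alternate-allele-rich at the tag sites, B =
# reference-rich), individuals receive a cluster-A allele dosage (0/1/2)
# from their two haplotypes, coding-mutation carriers are excluded, and
# dosage is regressed against age-at-onset phenotypes under an additive
# model (heterozygotes intermediate between the homozygote groups).

#' Default coding-variant exclusion list
#'
#' rsids of coding mutations known to alter the target gene's protein
#' function; individuals carrying any of these are removed before
#' haplotype-group association so that modifier-haplotype effects are
#' measured among idiopathic cases only.
#'
#' @return character vector of variant identifiers.
#' @export
default_exclusion_list <- function() {
  c("rs2230288", "rs75548401", "rs147138516", "rs76763715", "rs146774384",
    "L335")
}

haplotype_matrix <- function(haplotypes) {
  site_cols <- setdiff(names(haplotypes), c("haplotype_id", "count"))
  m <- as.matrix(haplotypes[, site_cols, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- haplotypes$haplotype_id
  m
}

#' Cluster distinct haplotypes into groups A and B
#'
#' Agglomerative hierarchical clustering of haplotype allele vectors
#' (0 = reference, 1 = alternate) on Euclidean distances with Ward's
#' minimum-variance criterion, dissimilarities squared before cluster
#' updating (`stats::hclust` method `"ward.D2"`; the unsquared `"ward.D"`
#' variant is available by flag). The tree is cut at k = 2 and the cluster
#' with the higher mean alternate-allele load at the designated tag sites
#' is labelled A. Distinct haplotypes are clustered unweighted by default;
#' `weight_by_count = TRUE` replicates each haplotype by its cohort count.
#' Haplotypes are sorted by `haplotype_id` before clustering, so the result
#' does not depend on input order.
#'
#' @param haplotypes data frame with columns `haplotype_id`, `count`, and
#'   one 0/1 column per variant site.
#' @param tag_sites site column names defining the A label; default all
#'   sites.
#' @param method `"ward.D2"` (default) or `"ward.D"`.
#' @param weight_by_count replicate haplotypes by cohort count before
#'   clustering (default `FALSE`).
#' @return list with `labels` (named character vector, `"A"`/`"B"` per
#'   haplotype id), `tree` (the `hclust` object), `tag_sites`, `k = 2`.
#' @export
cluster_haplotypes <- function(haplotypes, tag_sites = NULL,
                               method = c("ward.D2", "ward.D"),
                               weight_by_count = FALSE) {
  method <- match.arg(method)
  haplotypes <- haplotypes[order(haplotypes$haplotype_id), , drop = FALSE]
  m <- haplotype_matrix(haplotypes)
  if (is.null(tag_sites)) tag_sites <- colnames(m)
  if (!all(tag_sites %in% colnames(m))) {
    stop("tag_sites not among haplotype site columns", call. = FALSE)
  }
  if (nrow(m) < 2L) stop("need at least 2 haplotypes to cluster", call. = FALSE)
  if (nrow(unique(m)) < 2L) {
    stop("all haplotypes identical: no 2-cluster cut exists", call. = FALSE)
  }
  cm <- m
  if (weight_by_count) {
    cm <- m[rep(seq_len(nrow(m)), haplotypes$count), , drop = FALSE]
    rownames(cm) <- paste0(rep(rownames(m), haplotypes$count), ".",
                           sequence(haplotypes$count))
  }
  tree <- stats::hclust(stats::dist(cm, method = "euclidean"), method = method)
  cut <- stats::cutree(tree, k = 2)
  if (weight_by_count) {
    # project replicate labels back to distinct haplotypes (replicates of
    # one haplotype are identical points, so they share a cluster)
    cut <- cut[match(paste0(rownames(m), ".1"), names(cut))]
    names(cut) <- rownames(m)
  }
  load1 <- mean(m[cut == 1, tag_sites, drop = FALSE])
  load2 <- mean(m[cut == 2, tag_sites, drop = FALSE])
  a_cluster <- if (load1 > load2) 1L else if (load2 > load1) 2L else {
    # tie on tag load: the cluster not containing the smallest haplotype id
    # (the most prevalent, reference-rich haplotype sorts first) is A
    if (cut[[1L]] == 1L) 2L else 1L
  }
  labels <- ifelse(cut == a_cluster, "A", "B")
  names(labels) <- rownames(m)
  list(labels = labels, tree = tree, tag_sites = tag_sites, k = 2L)
}

parse_flags <- function(flags) {
  flags <- as.character(flags)
  flags[is.na(flags)] <- ""
  strsplit(flags, ";", fixed = TRUE)
}

#' Exclude coding-mutation carriers from a cohort
#'
#' Removes individuals whose `carrier_flags` (semicolon-separated variant
#' ids) intersect the exclusion list; the removal count is reported as a
#' message and attached as attribute `n_removed`.
#'
#' @param individuals data frame with columns `individual_id`, `hap1`,
#'   `hap2`, `carrier_flags`, plus phenotype columns.
#' @param exclusion character vector of variant ids
#'   (default [default_exclusion_list()]).
#' @return the retained subset of `individuals`.
#' @export
exclude_carriers <- function(individuals, exclusion = default_exclusion_list()) {
  flags <- parse_flags(individuals$carrier_flags)
  drop <- vapply(flags, function(f) any(f %in% exclusion), TRUE)
  message(sum(drop), " carrier(s) excluded; ", sum(!drop), " retained")
  out <- individuals[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Assign individuals to haplotype dosage groups
#'
#' Dosage is the count of cluster-A haplotype alleles carried (0, 1 or 2);
#' group 1 = homozygous cluster A (dosage 2), group 2 = heterozygous
#' (dosage 1), group 3 = homozygous cluster B (dosage 0).
#'
#' @param individuals data frame with `individual_id`, `hap1`, `hap2`.
#' @param clustering result of [cluster_haplotypes()].
#' @return data frame `individual_id`, `dosage`, `group`, with a
#'   `group_sizes` attribute (named counts for groups 1..3).
#' @export
assign_groups <- function(individuals, clustering) {
  labels <- clustering$labels
  missing <- setdiff(unique(c(individuals$hap1, individuals$hap2)), names(labels))
  if (length(missing)) {
    stop("haplotype(s) absent from clustering: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dosage <- (labels[individuals$hap1] == "A") + (labels[individuals$hap2] == "A")
  out <- data.frame(individual_id = individuals$individual_id,
                    dosage = as.integer(dosage),
                    group = 3L - as.integer(dosage),
                    stringsAsFactors = FALSE)
  attr(out, "group_sizes") <- stats::setNames(
    as.integer(table(factor(out$group, levels = 1:3))), c("1", "2", "3"))
  out
}

#' Additive (dosage) regression of a phenotype on haplotype groups
#'
#' Regresses a phenotype on the cluster-A allele dosage (0/1/2), the linear
#' coding of the ordered haplotype groups under an additive model. Reports
#' the Pearson correlation with its two-sided p-value, the OLS slope (per
#' cluster-A allele, in phenotype units), per-group means, and the
#' group 1 minus group 3 mean difference. Missing phenotypes are dropped
#' pairwise.
#'
#' @param assignments output of [assign_groups()].
#' @param phenotypes data frame with `individual_id` and phenotype columns.
#' @param phenotype name of the phenotype column to test.
#' @return list with `phenotype`, `pearson_r`, `p_value`, `slope`, `se`,
#'   `n`, `group_means` (named by group), `group_n`, `diff_g1_g3`.
#' @export
additive_regression <- function(assignments, phenotypes, phenotype) {
  if (!phenotype %in% names(phenotypes)) {
    stop("phenotype '", phenotype, "' not found", call. = FALSE)
  }
  d <- merge(assignments, phenotypes[, c("individual_id", phenotype)],
             by = "individual_id")
  y <- d[[phenotype]]
  ok <- !is.na(y)
  d <- d[ok, , drop = FALSE]; y <- y[ok]
  if (nrow(d) < 3L) stop("fewer than 3 individuals with phenotype", call. = FALSE)
  if (stats::var(y) == 0) stop("phenotype has zero variance", call. = FALSE)
  if (length(unique(d$dosage)) < 2L) stop("all individuals in one group", call. = FALSE)
  ct <- stats::cor.test(d$dosage, y, method = "pearson")
  fit <- ols_scalar(d$dosage, y)
  gm <- tapply(y, factor(d$group, levels = 1:3), mean)
  gn <- as.integer(table(factor(d$group, levels = 1:3)))
  list(
    phenotype = phenotype,
    pearson_r = unname(ct$estimate),
    p_value = ct$p.value,
    slope = fit$nes,
    se = fit$se,
    n = nrow(d),
    group_means = gm,
    group_n = stats::setNames(gn, c("1", "2", "3")),
    diff_g1_g3 = unname(gm["1"] - gm["3"])
  )
}
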