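#' Configuration for the two-strain divergence simulator
#'
#' Describes a clock-like world: a focal strain and a close relative that
#' split `T_split` generations ago, both diverging from the reference
#' (outgroup) lineage whose common ancestor lies `T_outgroup` generations
#' back. Mutations accumulate under the infinite-sites model at per-site
#' rate `mu` per generation. Shared ancestral heterozygosity — the dominant
#' signal in closely related tetraploid beer strains — is injected at
#' per-site rate `theta_anc` in both strains.
#'
#' Defaults mirror the scale inferred for closely related industrial
#' brewing strains: `mu = 1.67e-10` substitutions/site/generation,
#' a reference divergence of 1.4e7 generations and a focal/relative split
#' at 0.24% of that depth.
#'
#' @param n_syn_sites,n_nonsyn_sites number of synonymous / nonsynonymous
#'   coding sites simulated.
#' @param mu per-site per-generation mutation rate.
#' @param T_outgroup generations to the common ancestor with the reference.
#' @param T_split generations since the focal/relative split.
#' @param theta_anc expected shared ancestral heterozygous variants per site.
#' @param ploidy strain ploidy (both strains).
#' @param seed integer RNG seed.
#' @return a `PopSimConfig` list.
#' @export
pop_sim_config <- function(n_syn_sites = 2e5, n_nonsyn_sites = 4e5,
                           mu = 1.67e-10, T_outgroup = 1.4e7,
                           T_split = 33600, theta_anc = 0.002,
                           ploidy = 4L, seed = NULL) {
  check_scalar(T_split, "T_split", 0)
  check_scalar(T_outgroup, "T_outgroup", 0)
  if (T_split > T_outgroup) bt_stop("config", "T_split must be <= T_outgroup")
  check_scalar(mu, "mu", 0)
  check_scalar(theta_anc, "theta_anc", 0, 1)
  if (!is_count(n_syn_sites) || !is_count(n_nonsyn_sites))
    bt_stop("config", "site counts must be non-negative integers")
  if (!is_count(ploidy) || ploidy < 1) bt_stop("config", "ploidy must be >= 1")
  structure(list(n_syn_sites = n_syn_sites, n_nonsyn_sites = n_nonsyn_sites,
                 mu = mu, T_outgroup = T_outgroup, T_split = T_split,
                 theta_anc = theta_anc, ploidy = as.integer(ploidy),
                 seed = seed),
            class = "PopSimConfig")
}

#' Simulate a focal/relative strain pair diverging from a reference
#'
#' Mutations are placed on three branches of the assumed tree, with Poisson
#' counts of mean `mu * branch_length * n_sites` per site class:
#' \describe{
#'   \item{focal-private}{branch length `T_split`; carried only by the focal
#'     strain.}
#'   \item{relative-private}{branch length `T_split`; carried only by the
#'     relative.}
#'   \item{shared-vs-reference}{the path from the focal/relative split node
#'     down to the common ancestor and up the reference lineage, length
#'     `2*T_outgroup - T_split`; these variants are carried by both strains
#'     and distinguish them from the reference.}
#' }
#' With this bookkeeping the expected pairwise focal-vs-reference divergence
#' is `2 * mu * T_outgroup` per site, as a molecular clock requires, and the
#' branch-fraction estimator recovers `T_split / T_outgroup`.
#'
#' Divergence mutations are fixed within a lineage (homozygous alternate);
#' shared ancestral heterozygosity is injected at rate `theta_anc` as
#' half-dosage genotypes in both strains. Each variant occupies a distinct
#' site (infinite sites).
#'
#' @param cfg a [pop_sim_config()].
#' @return list with `vt` (a [variant_table()] of the variant sites only,
#'   with a `SYN` flag annotation; strains `focal` and `relative`) and
#'   `truth` (branch counts, injected heterozygous site count, `T_split`,
#'   `T_outgroup` and the true branch fraction `f_true`).
#' @export
simulate_population <- function(cfg = pop_sim_config()) {
  stopifnot(inherits(cfg, "PopSimConfig"))
  total_len <- 2 * cfg$T_outgroup + cfg$T_split  # sum of the three branches
  if (cfg$mu * total_len > 0.1)
    bt_stop("infinite_sites",
            "expected mutations per site (%.3g) exceed the infinite-sites regime",
            cfg$mu * total_len)

  with_seed(cfg$seed, {
    branch_len <- c(focal_private = cfg$T_split,
                    relative_private = cfg$T_split,
                    shared = 2 * cfg$T_outgroup - cfg$T_split)
    classes <- list(syn = cfg$n_syn_sites, nonsyn = cfg$n_nonsyn_sites)
    out <- list()
    truth_counts <- list()
    for (cl in names(classes)) {
      n_sites <- classes[[cl]]
      counts <- rpois(3, cfg$mu * branch_len * n_sites)
      names(counts) <- names(branch_len)
      n_anc <- rbinom(1, n_sites, cfg$theta_anc)
      n_var <- sum(counts) + n_anc
      if (n_var > n_sites)
        bt_stop("infinite_sites", "more variants than sites in class '%s'", cl)
      pos <- sort(sample.int(n_sites, n_var)) - 1L
      role <- rep(c(names(counts), "anc_het"), times = c(counts, n_anc))
      role <- sample(role)  # detach role from position ordering
      out[[cl]] <- data.table(pos = pos, role = role, syn = (cl == "syn"))
      truth_counts[[cl]] <- c(counts, anc_het = n_anc)
    }
    sites <- rbindlist(list(out$syn, out$nonsyn[, .(pos = pos + cfg$n_syn_sites,
                                                    role, syn)]))
    p <- cfg$ploidy
    half <- max(1L, p %/% 2L)
    gt_of <- function(dosage) {
      vapply(dosage, function(d)
        paste(c(rep("0", p - d), rep("1", d)), collapse = "/"), character(1))
    }
    dose_focal <- ifelse(sites$role == "focal_private", p,
                  ifelse(sites$role == "shared", p,
                  ifelse(sites$role == "anc_het", half, 0L)))
    dose_rel <- ifelse(sites$role == "relative_private", p,
                ifelse(sites$role == "shared", p,
                ifelse(sites$role == "anc_het", half, 0L)))

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, nrow(sites), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

    vt <- variant_table(
      sites = data.table(chrom = "concat", pos = sites$pos, ref = ref, alt = alt),
      gt = matrix(c(gt_of(dose_focal), gt_of(dose_rel)), ncol = 2,
                  dimnames = list(NULL, c("focal", "relative"))),
      ploidy = c(focal = p, relative = p),
      site_ann = data.table(SYN = sites$syn)
    )
    list(vt = vt,
         truth = list(counts = truth_counts,
                      n_syn_sites = cfg$n_syn_sites,
                      n_nonsyn_sites = cfg$n_nonsyn_sites,
                      T_split = cfg$T_split, T_outgroup = cfg$T_outgroup,
                      f_true = cfg$T_split / cfg$T_outgroup,
                      config = cfg))
  })
}
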