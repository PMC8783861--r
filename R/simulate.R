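#' Cohort design for the simulator
#'
#' Group sizes for a three-subgroup lung adenocarcinoma cohort in which
#' only the ALK/EGFR-negative patients received immune checkpoint
#' blockade and are therefore split by response (long-term responders,
#' intermediate responders, rapid progressors).  Defaults reproduce the
#' 114-sample study design: 31 ALK, 40 EGFR, 43 NEG = 16 LTR + 6 IR +
#' 21 RP.
#'
#' @param n_alk,n_egfr Sizes of the ALK- and EGFR-positive groups.
#' @param n_ltr,n_ir,n_rp Response split of the ALK/EGFR-negative group.
#' @param covariates Covariate columns to emit (`smoking`, `tp53`).
#' @return A `cohort_design` list with `sizes` and `covariates`.
#' @export
#' @examples
#' cohort_design()
cohort_design <- function(n_alk = 31, n_egfr = 40,
                          n_ltr = 16, n_ir = 6, n_rp = 21,
                          covariates = c("smoking", "tp53")) {
  sizes <- c(ALK = n_alk, EGFR = n_egfr, LTR = n_ltr, IR = n_ir,
             RP = n_rp)
  if (any(sizes < 0)) abort("group sizes must be nonnegative")
  structure(list(sizes = sizes, covariates = covariates),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  s <- x$sizes
  cat(sprintf("<cohort_design> ALK %d / EGFR %d / NEG %d (LTR %d, IR %d, RP %d)\n",
              s["ALK"], s["EGFR"], s["LTR"] + s["IR"] + s["RP"],
              s["LTR"], s["IR"], s["RP"]))
  invisible(x)
}

#' Packaged planted-effect contrasts
#'
#' The signed fold-change contrasts planted by default in simulated
#' cohorts: higher Tregs in ALK-positive tumors (fold change 2.1 vs the
#' ALK/EGFR-negative group, 1.9 vs the EGFR-positive group) and lower
#' cytotoxic cells in EGFR-positive tumors (fold change -2.1 vs the
#' negative group) — the headline immune-composition differences the
#' pipeline is expected to recover.
#'
#' @return Tibble with columns `population`, `group_a`, `group_b`, `fc`
#'   (signed convention: negative means lower in `group_a`).
#' @export
planted_effects <- function() {
  readr::read_tsv(system.file("extdata", "planted_effects.tsv",
                              package = "immunoscape"),
                  show_col_types = FALSE, progress = FALSE)
}

# Signed fold change -> multiplicative ratio a/b.
fc_to_ratio <- function(fc) ifelse(fc >= 0, fc, -1 / fc)

# Solve per-(population, group) multipliers from signed contrasts,
# anchoring the NEG group (and any unconstrained group) at 1.
effects_from_contrasts <- function(contrasts) {
  if (is.null(contrasts) || nrow(contrasts) == 0) {
    return(tibble(population = character(), group = character(),
                  multiplier = numeric()))
  }
  stopifnot(all(c("population", "group_a", "group_b", "fc") %in%
                  names(contrasts)))
  if (any(abs(contrasts$fc) < 1)) {
    abort("signed fold changes have magnitude >= 1 by convention")
  }
  out <- list()
  for (pop in unique(contrasts$population)) {
    cc <- contrasts[contrasts$population == pop, ]
    mult <- c(NEG = 1)
    # propagate until all groups mentioned are assigned
    remaining <- cc
    repeat {
      progressed <- FALSE
      keep <- rep(TRUE, nrow(remaining))
      for (i in seq_len(nrow(remaining))) {
        a <- remaining$group_a[i]; b <- remaining$group_b[i]
        r <- fc_to_ratio(remaining$fc[i])
        if (a %in% names(mult) && !b %in% names(mult)) {
          mult[b] <- mult[[a]] / r; progressed <- TRUE; keep[i] <- FALSE
        } else if (b %in% names(mult) && !a %in% names(mult)) {
          mult[a] <- mult[[b]] * r; progressed <- TRUE; keep[i] <- FALSE
        } else if (a %in% names(mult) && b %in% names(mult)) {
          if (abs(log(mult[[a]] / mult[[b]]) - log(r)) > 1e-8) {
            abort(sprintf("inconsistent contrasts for population '%s'", pop))
          }
          keep[i] <- FALSE
        }
      }
      remaining <- remaining[keep, ]
      if (nrow(remaining) == 0) break
      if (!progressed) {
        # disconnected component: anchor its first group at 1
        mult[remaining$group_a[1]] <- 1
      }
    }
    out[[pop]] <- tibble(population = pop, group = names(mult),
                         multiplier = unname(mult))
  }
  list_rbind(out)
}

#' Effect and noise specification for the simulator
#'
#' Bundles everything the negative-binomial count model needs: per-gene
#' baseline means and dispersions, planted group-specific multipliers on
#' marker genes, lane-factor spread, and control-probe parameters.
#'
#' @param panel A `panel_spec` from [io_panel()].
#' @param contrasts Signed fold-change contrasts
#'   (`population`, `group_a`, `group_b`, `fc`), e.g.
#'   [planted_effects()]; `NULL` plants no effects.
#' @param sigma_bio Between-sample biological spread of each latent
#'   population score, in log2 units (default 0.5).
#' @param sigma_gene Per-gene biological spread (log2 units) applied to
#'   every endogenous gene (default 0.4).
#' @param lane_sdlog Log-normal sdlog of the per-lane scale factor
#'   (default 0.15).
#' @param bg_mean Poisson background mean added to every probe and the
#'   only signal on negative controls (default 5 counts).
#' @param dispersion Negative-binomial size parameter shared by
#'   endogenous genes (default 20).
#' @param pos_slope Expected counts per fM for positive controls
#'   (default 30).
#' @param pos_size Negative-binomial size for positive-control probes
#'   (default 2000: spike-in hybridization is nearly Poisson, with no
#'   biological dispersion).
#' @param seed Seed for drawing the per-gene baselines.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(panel, contrasts = NULL, sigma_bio = 0.5,
                        sigma_gene = 0.4, lane_sdlog = 0.15,
                        bg_mean = 5, dispersion = 20, pos_slope = 30,
                        pos_size = 2000, seed = 1L) {
  validate_panel(panel)
  stopifnot(dispersion > 0, sigma_bio >= 0, bg_mean >= 0)
  set.seed(seed)
  genes <- panel$endogenous
  is_marker <- genes %in% panel$marker_map$gene
  mu <- exp(rnorm(length(genes), log(80), 1))
  mu[is_marker] <- exp(rnorm(sum(is_marker), log(250), 0.4))
  gene_params <- tibble(
    gene = genes,
    mu = mu,
    size = dispersion
  )
  hk_params <- tibble(
    gene = panel$housekeeping,
    mu = exp(rnorm(length(panel$housekeeping), log(600), 0.15)),
    size = 4 * dispersion  # housekeepers are tight by construction
  )
  structure(
    list(gene_params = gene_params, hk_params = hk_params,
         multipliers = effects_from_contrasts(contrasts),
         contrasts = contrasts,
         sigma_bio = sigma_bio, sigma_gene = sigma_gene,
         lane_sdlog = lane_sdlog, bg_mean = bg_mean,
         pos_slope = pos_slope, pos_size = pos_size, seed = seed),
    class = "effect_spec")
}

#' Simulate an nCounter-like cohort with known ground truth
#'
#' Draws a full probe-by-sample count matrix from a negative-binomial
#' model: per-gene baseline means, a latent per-sample biological factor
#' for each immune population (shared by all of its marker genes, so the
#' population score shifts by exactly the planted log2 fold change in
#' expectation), per-gene biological noise, a log-normal per-lane scale
#' factor multiplying all probes, positive controls proportional to
#' their nominal concentration times the lane factor, and a Poisson
#' background that is the only signal on negative controls.
#'
#' @param design A [cohort_design()].
#' @param panel A [io_panel()] specification.
#' @param effects An [effect_spec()]; defaults to no planted effects.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `sim_cohort` list: `counts` (wide count-matrix tibble),
#'   `metadata` (per-sample tibble), `truth` (planted multipliers and
#'   the signed fold changes they imply for the standard contrasts),
#'   `lane_factors` (the true per-lane scale factors), and the
#'   `design`, `panel`, `effects`, `seed` used.
#' @export
#' @examples
#' sim <- simulate_cohort(cohort_design(), io_panel(n_genes = 200), seed = 7)
#' dim(sim$counts)
simulate_cohort <- function(design = cohort_design(),
                            panel = io_panel(),
                            effects = effect_spec(panel),
                            seed = 1L) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(effects, "effect_spec"))
  validate_panel(panel)
  s <- design$sizes
  groups <- c(rep("ALK", s["ALK"]), rep("EGFR", s["EGFR"]),
              rep("LTR", s["LTR"]), rep("IR", s["IR"]),
              rep("RP", s["RP"]))
  n <- length(groups)
  if (n == 0) abort("cohort design has no samples")
  planted_groups <- unique(effects$multipliers$group[
    abs(log(effects$multipliers$multiplier)) > 1e-12])
  sizes_by_key <- c(s, NEG = unname(s["LTR"] + s["IR"] + s["RP"]))
  empty <- planted_groups[sizes_by_key[planted_groups] == 0]
  if (length(empty)) {
    abort(paste0("planted contrast on empty group(s): ",
                 paste(empty, collapse = ", ")))
  }

  set.seed(seed)
  metadata <- tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    subgroup = ifelse(groups %in% c("LTR", "IR", "RP"), "NEG", groups),
    icb_response = ifelse(groups %in% c("LTR", "IR", "RP"), groups,
                          NA_character_)
  )
  if ("smoking" %in% design$covariates) {
    p_smoke <- c(ALK = 0.3, EGFR = 0.4, NEG = 0.95)[metadata$subgroup]
    metadata$smoking <- ifelse(runif(n) < p_smoke, "smoker", "nonsmoker")
  }
  if ("tp53" %in% design$covariates) {
    metadata$tp53 <- ifelse(runif(n) < 0.5, "mut", "wt")
  }

  lane_factor <- exp(rnorm(n, 0, effects$lane_sdlog))

  gp <- effects$gene_params
  genes <- gp$gene
  mu <- matrix(gp$mu, nrow = length(genes), ncol = n,
               dimnames = list(genes, metadata$sample_id))

  # planted group multipliers on marker genes (IR follows RP unless the
  # effect spec addresses IR explicitly)
  mult <- effects$multipliers
  if (nrow(mult)) {
    eff_groups <- groups
    if (!"IR" %in% mult$group) eff_groups[eff_groups == "IR"] <- "RP"
    for (i in seq_len(nrow(mult))) {
      g <- mult$group[i]
      in_group <- if (g == "NEG") metadata$subgroup == "NEG" else eff_groups == g
      mk <- panel$marker_map$gene[panel$marker_map$population ==
                                    mult$population[i]]
      mk <- intersect(mk, genes)
      mu[mk, in_group] <- mu[mk, in_group] * mult$multiplier[i]
    }
  }

  # latent per-sample population factors, shared across a population's
  # markers so the score inherits sigma_bio exactly
  pops <- unique(panel$marker_map$population)
  for (p in pops) {
    f <- 2^rnorm(n, 0, effects$sigma_bio)
    mk <- intersect(panel$marker_map$gene[panel$marker_map$population == p],
                    genes)
    mu[mk, ] <- sweep(mu[mk, , drop = FALSE], 2, f, `*`)
  }
  # independent per-gene biological noise
  mu <- mu * 2^matrix(rnorm(length(mu), 0, effects$sigma_gene),
                      nrow = nrow(mu))

  mu <- sweep(mu, 2, lane_factor, `*`)
  counts_endo <- matrix(
    rnbinom(length(mu), mu = mu, size = gp$size) +
      rpois(length(mu), effects$bg_mean),
    nrow = nrow(mu), dimnames = dimnames(mu))

  hk <- effects$hk_params
  mu_hk <- outer(hk$mu, lane_factor)
  counts_hk <- matrix(
    rnbinom(length(mu_hk), mu = mu_hk, size = hk$size) +
      rpois(length(mu_hk), effects$bg_mean),
    nrow = nrow(mu_hk), dimnames = list(hk$gene, metadata$sample_id))

  mu_pos <- outer(effects$pos_slope * panel$positives$concentration,
                  lane_factor)
  counts_pos <- matrix(
    rnbinom(length(mu_pos), mu = mu_pos, size = effects$pos_size) +
      rpois(length(mu_pos), effects$bg_mean),
    nrow = nrow(mu_pos),
    dimnames = list(panel$positives$probe, metadata$sample_id))

  counts_neg <- matrix(
    rpois(length(panel$negatives) * n, effects$bg_mean),
    nrow = length(panel$negatives),
    dimnames = list(panel$negatives, metadata$sample_id))

  counts <- bind_rows(
    bind_cols(tibble(gene = genes, probe_class = "Endogenous",
                     concentration = NA_real_),
              as_tibble(counts_endo)),
    bind_cols(tibble(gene = hk$gene, probe_class = "Housekeeping",
                     concentration = NA_real_),
              as_tibble(counts_hk)),
    bind_cols(tibble(gene = panel$positives$probe,
                     probe_class = "Positive",
                     concentration = panel$positives$concentration),
              as_tibble(counts_pos)),
    bind_cols(tibble(gene = panel$negatives, probe_class = "Negative",
                     concentration = NA_real_),
              as_tibble(counts_neg)))
  validate_counts(counts)

  truth <- truth_table(effects)
  structure(
    list(counts = counts, metadata = metadata, truth = truth,
         lane_factors = tibble(sample_id = metadata$sample_id,
                               lane_factor = lane_factor),
         design = design, panel = panel, effects = effects, seed = seed),
    class = "sim_cohort")
}

# Planted signed fold changes for the standard contrasts, derived from
# the group multipliers (1 where no effect was planted).
truth_table <- function(effects) {
  std <- tibble(group_a = c("ALK", "EGFR", "ALK", "ALK", "EGFR", "EGFR"),
                group_b = c("NEG", "NEG", "EGFR", "RP", "RP", "LTR"))
  mult <- effects$multipliers
  pops <- unique(mult$population)
  if (!length(pops)) {
    return(tibble(population = character(), group_a = character(),
                  group_b = character(), planted_fc = numeric()))
  }
  get_mult <- function(pop, grp) {
    m <- mult$multiplier[mult$population == pop & mult$group == grp]
    if (length(m)) m else {
      # response groups fall back to NEG's multiplier
      if (grp %in% c("LTR", "IR", "RP")) get_mult(pop, "NEG") else 1
    }
  }
  out <- list()
  for (pop in pops) {
    ratio <- map_dbl(seq_len(nrow(std)), function(i) {
      get_mult(pop, std$group_a[i]) / get_mult(pop, std$group_b[i])
    })
    out[[pop]] <- bind_cols(tibble(population = pop), std,
                            tibble(planted_fc = ifelse(ratio >= 1, ratio,
                                                       -1 / ratio)))
  }
  list_rbind(out)
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d probes x %d samples (seed %d)\n",
              nrow(x$counts), nrow(x$metadata), x$seed))
  invisible(x)
}

#' Simulate a reference expression table for housekeeper selection
#'
#' Emulates a large-cohort RNA-seq reference (linear scale) in which the
#' panel's designated housekeeping genes are highly and stably expressed
#' (coefficient of variation about 0.02, mean well above 100) while
#' endogenous genes vary several-fold between samples, so that the
#' data-driven selection rule in [select_housekeepers()] recovers the
#' packaged housekeeper list.
#'
#' @param panel A `panel_spec`.
#' @param n_samples Number of reference samples (>= 2).
#' @param seed Integer seed.
#' @return Wide tibble: `gene` plus one linear-scale column per sample.
#' @export
simulate_reference <- function(panel, n_samples = 50, seed = 1L) {
  validate_panel(panel)
  if (n_samples < 2) {
    abort("n_samples must be >= 2 (coefficient of variation undefined)")
  }
  set.seed(seed)
  genes <- c(panel$endogenous, panel$housekeeping)
  is_hk <- genes %in% panel$housekeeping
  mean_expr <- exp(rnorm(length(genes), log(150), 1.2))
  mean_expr[is_hk] <- exp(rnorm(sum(is_hk), log(800), 0.2))
  sdlog <- ifelse(is_hk, 0.02, 0.3)
  vals <- matrix(
    exp(rnorm(length(genes) * n_samples, log(mean_expr), sdlog)),
    nrow = length(genes),
    dimnames = list(genes, sprintf("REF%03d", seq_len(n_samples))))
  bind_cols(tibble(gene = genes), as_tibble(vals))
}
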