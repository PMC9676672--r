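# Seeded generator of synthetic datasets with the statistical structure
# the analysis assumes: K well-separated COI sequence clusters, companion
# 18S sequences that collapse designated clusters to identical sequence,
# and two-morphotype measurement tables.
#
# Divergence model: a random ancestral sequence is mutated at
# ceiling(d_between * L) sites to form each group founder, with the
# mutated site sets DISJOINT across groups so between-group divergence is
# controllable (a deliberate departure from a coalescent, for
# testability); each member then mutates its founder at
# Binomial(L, d_within) sites, substitutions drawing uniformly from the
# three other bases (Jukes-Cantor-like). No indels.

BASES <- c("A", "C", "G", "T")

#' Simulation parameters
#'
#' Defaults mirror the study conditions at desk scale: a 393-position
#' COI-length alignment, tight within-cluster divergence (~1.5%), wide
#' between-cluster divergence (>= 15%), six clusters of five specimens
#' (the corridor-clade structure), a 600-position companion 18S sequence
#' per collapse class, and morphotype measurement distributions centred
#' on the observed short- and long-tailed values.
#'
#' @param K number of sequence clusters (>= 1).
#' @param n_per_group members per cluster; scalar or length-`K` vector.
#' @param L alignment length in positions.
#' @param d_within expected within-cluster per-site divergence fraction.
#' @param d_between per-founder divergence fraction from the ancestor;
#'   founder site sets are disjoint, so two groups differ at about
#'   `2 * d_between * L` sites.
#' @param collapse_map named list mapping a coarse 18S label to the
#'   cluster indices sharing one identical 18S sequence; clusters not
#'   listed each get their own.  `NULL` (default) gives every cluster its
#'   own 18S sequence.
#' @param ssu_length length of the companion 18S sequences.
#' @param morph_params per-morphotype (short/long) mean and sd of the c'
#'   ratio, anal body width, amphid/neck ratio and neck width, from which
#'   tail length and amphid width are derived.
#' @param morphotype_of length-`K` character vector assigning each
#'   cluster a morphotype; default alternates, first half short.
#' @param seed integer seed; the whole dataset is reproducible.
#' @return a validated list of class `"sim_params"`.
#' @export
sim_params <- function(K = 6L, n_per_group = 5L, L = 393L,
                       d_within = 0.015, d_between = 0.15,
                       collapse_map = NULL, ssu_length = 600L,
                       morph_params = default_morph_params(),
                       morphotype_of = NULL, seed = 1L) {
  if (K < 1L) value_error("K must be >= 1")
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, K)
  if (length(n_per_group) != K || any(n_per_group < 1L))
    value_error("n_per_group must be positive, one count per group")
  if (!(d_within >= 0 && d_within < d_between && d_between <= 0.75))
    value_error("need 0 <= d_within < d_between <= 0.75")
  n_founder_sites <- ceiling(d_between * L)
  if (K * n_founder_sites > L)
    value_error(sprintf(
      "cannot place %d disjoint founder site sets of %d in %d positions",
      K, n_founder_sites, L))
  if (is.null(morphotype_of))
    morphotype_of <- rep(c("short", "long"), each = ceiling(K / 2))[seq_len(K)]
  if (!all(morphotype_of %in% c("short", "long")) ||
      length(morphotype_of) != K)
    value_error("morphotype_of must be 'short'/'long', one per group")
  if (is.null(collapse_map))
    collapse_map <- stats::setNames(as.list(seq_len(K)),
                                    sprintf("ssu_%d", seq_len(K)))
  idx <- sort(unlist(collapse_map))
  if (!identical(as.integer(idx), seq_len(K)))
    value_error("collapse_map must cover each group index exactly once")
  structure(list(K = as.integer(K), n_per_group = as.integer(n_per_group),
                 L = as.integer(L), d_within = d_within,
                 d_between = d_between, collapse_map = collapse_map,
                 ssu_length = as.integer(ssu_length),
                 morph_params = morph_params,
                 morphotype_of = morphotype_of, seed = as.integer(seed)),
            class = "sim_params")
}

#' Default morphotype measurement distributions
#'
#' Means and standard deviations per morphotype, chosen from the
#' empirical ranges of the corridor voucher measurements: short-tailed
#' specimens with c' near 2.4 and amphid/neck ratio near 0.14,
#' long-tailed with c' near 5.2 and ratio near 0.26.
#'
#' @return nested list `morphotype -> measurement -> c(mean, sd)`.
#' @export
default_morph_params <- function() {
  list(short = list(c_prime = c(mean = 2.4, sd = 0.25),
                    anal_body_width = c(mean = 27, sd = 4.5),
                    amphid_ratio = c(mean = 0.14, sd = 0.03),
                    neck_width = c(mean = 16.5, sd = 2.3)),
       long = list(c_prime = c(mean = 5.2, sd = 0.4),
                   anal_body_width = c(mean = 18.5, sd = 3),
                   amphid_ratio = c(mean = 0.26, sd = 0.03),
                   neck_width = c(mean = 14.7, sd = 1.9)))
}

random_seq <- function(L) sample(BASES, L, replace = TRUE)

# substitute: replace positions `sites` with a uniformly chosen base
# different from the current one
mutate_sites <- function(seq, sites) {
  if (length(sites) == 0L) return(seq)
  seq[sites] <- vapply(seq[sites], function(b)
    sample(setdiff(BASES, b), 1L), character(1))
  seq
}

# normal draw truncated at 0 (redraw; these distributions are many sds
# from 0 so this rarely loops)
rnorm_pos <- function(n, ms) {
  x <- stats::rnorm(n, ms["mean"], ms["sd"])
  while (any(x <= 0))
    x[x <= 0] <- stats::rnorm(sum(x <= 0), ms["mean"], ms["sd"])
  x
}

#' Simulate a synthetic barcoding dataset
#'
#' @param params a [sim_params()].
#' @return a list of class `"synthetic_dataset"` with elements `coi`
#'   (a `plectax_alignment`), `ssu` (companion 18S alignment, identical
#'   within each collapse class), `truth` (a `group_partition` assigning
#'   every sequence), `morph` (measurement data.frame with a
#'   `true_morphotype` column) and `params`.
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    K <- params$K; L <- params$L
    nf <- ceiling(params$d_between * L)
    ancestor <- random_seq(L)
    founder_sites <- split(sample.int(L, K * nf),
                           rep(seq_len(K), each = nf))
    ids <- character(0); groups <- character(0)
    rows <- list()
    for (k in seq_len(K)) {
      founder <- mutate_sites(ancestor, founder_sites[[k]])
      for (i in seq_len(params$n_per_group[k])) {
        m <- stats::rbinom(1L, L, params$d_within)
        member <- mutate_sites(founder, sample.int(L, m))
        id <- sprintf("g%02d_%02d", k, i)
        ids <- c(ids, id); groups <- c(groups, sprintf("group_%d", k))
        rows[[id]] <- member
      }
    }
    coi <- alignment(do.call(rbind, rows)[ids, , drop = FALSE])
    rownames(coi) <- ids

    # one fixed 18S sequence per collapse class, copied to all members
    ssu_of_group <- character(K)
    for (lab in names(params$collapse_map)) {
      s <- paste(random_seq(params$ssu_length), collapse = "")
      ssu_of_group[unlist(params$collapse_map[[lab]])] <- s
    }
    group_index <- as.integer(sub("group_", "", groups))
    ssu <- alignment(stats::setNames(ssu_of_group[group_index], ids))

    morphotype <- params$morphotype_of[group_index]
    morph <- do.call(rbind, lapply(seq_along(ids), function(i) {
      mp <- params$morph_params[[morphotype[i]]]
      abw <- rnorm_pos(1, mp$anal_body_width)
      cp <- rnorm_pos(1, mp$c_prime)
      neck <- rnorm_pos(1, mp$neck_width)
      ratio <- rnorm_pos(1, mp$amphid_ratio)
      data.frame(nid = ids[i],
                 stage = sample(c("F", "J"), 1L, prob = c(0.6, 0.4)),
                 tail_length = cp * abw, anal_body_width = abw,
                 amphid_width = ratio * neck, neck_width = neck,
                 true_morphotype = morphotype[i])
    }))

    truth <- structure(
      list(assignment = stats::setNames(groups, ids),
           provenance = data.frame()),
      class = "group_partition")
    structure(list(coi = coi, ssu = ssu, truth = truth, morph = morph,
                   params = params),
              class = "synthetic_dataset")
  })
}

#' Expected within-group pairwise p-distance
#'
#' Two members mutate their common founder independently; a site is
#' mutated with marginal probability `d` (a Binomial(L, d) site count
#' spread uniformly over distinct sites leaves the per-site marginal at
#' exactly `d`).  At a given site the pair differs when exactly one
#' member mutated (probability `2 d (1 - d)`) or both mutated and drew
#' different replacement bases (probability `d^2 * 2/3`, replacements
#' uniform over the three non-founder bases).  Hence
#' `E[p] = 2 d (1 - d) + (2/3) d^2`, exactly, by linearity over sites.
#'
#' @param d_within per-site mutation fraction (or a [sim_params()]).
#' @return expected pairwise p-distance between two group members.
#' @export
expected_within_distance <- function(d_within) {
  d <- if (inherits(d_within, "sim_params")) d_within$d_within else d_within
  2 * d * (1 - d) + (2 / 3) * d^2
}

#' Write a synthetic dataset as a plain-text fixture bundle
#'
#' Emits `coi.fasta`, `ssu.fasta`, `truth_groups.tsv`, `morph.tsv` and
#' `params.json` under `dir`; all re-readable with the package's readers.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    abort(sprintf("cannot create directory: %s", dir), "plectax_io_error")
  write_alignment(ds$coi, file.path(dir, "coi.fasta"))
  write_alignment(ds$ssu, file.path(dir, "ssu.fasta"))
  utils::write.table(
    data.frame(nid = names(ds$truth$assignment),
               group = unname(ds$truth$assignment)),
    file.path(dir, "truth_groups.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$morph, file.path(dir, "morph.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  p <- unclass(ds$params)
  jsonlite::write_json(p, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Truth-recovery rate of the delimitation pipeline on simulated data
#'
#' Runs the full pipeline (simulate -> p-distances -> bootstrap NJ ->
#' delimit) `n_runs` times with consecutive seeds and reports the
#' fraction of runs in which the delimited partition equals the
#' generating one (adjusted Rand index 1 and no unassigned members).
#'
#' @param params a [sim_params()]; its `seed` seeds the first run, run
#'   `r` uses `seed + r - 1`.
#' @param n_runs number of seeded runs.
#' @param replicates bootstrap replicates per run.
#' @param criteria a [delimitation_criteria()].
#' @return list with `rate`, `ari` (per-run adjusted Rand index) and
#'   `n_unassigned` (per run).
#' @export
delimitation_recovery <- function(params, n_runs = 20L, replicates = 200L,
                                  criteria = delimitation_criteria()) {
  ari <- numeric(n_runs)
  n_un <- integer(n_runs)
  for (r in seq_len(n_runs)) {
    p <- params
    p$seed <- params$seed + r - 1L
    ds <- simulate_dataset(p)
    tree <- bootstrap_supports(ds$coi, replicates = replicates,
                               seed = p$seed + 10000L)
    part <- delimit(tree, p_distance_matrix(ds$coi), criteria)
    est <- part$assignment[names(ds$truth$assignment)]
    n_un[r] <- sum(est == unassigned_label())
    ari[r] <- mclust::adjustedRandIndex(est, ds$truth$assignment)
  }
  exact <- ari == 1 & n_un == 0
  list(rate = mean(exact), ari = ari, n_unassigned = n_un)
}
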