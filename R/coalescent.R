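## Multispecies coalescent with stepwise copy-number mutation.
##
## Time convention: coalescent units of 4*Ne_ref generations. Within a
## population of relative size x = Ne_pop/Ne_ref holding j lineages, the
## next coalescence is exponential with rate choose(j, 2)/x, so for two
## samples in a reference-size population E[TMRCA] = 1 and the expected
## number of pairwise mutations at scaled rate theta is theta (mutations
## are Poisson with mean theta/2 per unit branch length).

#' Population-scaled mutation rate from a per-Myr event rate
#'
#' Converts a copy-number mutation rate of `k` events per million years
#' into the population-scaled `theta = 4 * Ne * mu` with
#' `mu = k * genTime / 1e6` per generation. With the default human
#' parameters (Ne = 1e4, 25-year generations) `theta == k`.
#'
#' @param k Mutational events (copy gain or loss) per million years.
#' @param Ne Effective population size.
#' @param genTime Generation time in years.
#' @return Scaled mutation rate theta.
#' @examples
#' thetaFromK(1)    # 1
#' thetaFromK(5.5)  # 5.5
#' @export
thetaFromK <- function(k, Ne = 1e4, genTime = 25) {
  stopifnot(all(k > 0), Ne > 0, genTime > 0)
  4 * Ne * (k * genTime / 1e6)
}

#' Specify a multispecies population model
#'
#' @param tree Ultrametric [ape::phylo] species tree with branch lengths
#'   in million years, or `NULL` for a single population.
#' @param species Species names (defaults to tree tip labels).
#' @param samples Named integer vector: haploid sample count per species.
#' @param Ne Named vector of effective population sizes; unnamed species
#'   default to `NeRef`.
#' @param NeRef Reference (human) effective population size.
#' @param genTime Generation time in years.
#' @return A list of class `popModel` with divergence events converted to
#'   coalescent units of `4 * NeRef` generations.
#' @export
popModel <- function(tree = NULL, species = NULL, samples,
                     Ne = NULL, NeRef = 1e4, genTime = 25) {
  if (!is.null(tree)) {
    .checkUltrametric(tree)
    species <- tree$tip.label
  }
  if (is.null(species)) species <- names(samples)
  if (is.null(names(samples)) && length(samples) == length(species))
    names(samples) <- species
  stopifnot(all(species %in% names(samples)))
  samples <- samples[species]
  x <- rep(1, length(species))
  names(x) <- species
  if (!is.null(Ne)) x[names(Ne)] <- Ne / NeRef
  events <- NULL
  if (!is.null(tree) && length(species) > 1L) {
    ages_myr <- .nodeAges(tree)
    ntip <- ape::Ntip(tree)
    # coalescent-unit conversion: t_years / (genTime * 4 * NeRef)
    to_cu <- function(myr) myr * 1e6 / (genTime * 4 * NeRef)
    internal <- order(ages_myr[-seq_len(ntip)]) + ntip
    events <- data.frame(node = internal,
                         time = to_cu(ages_myr[internal]))
    if (is.unsorted(events$time))
      stop("divergence times inconsistent with tree traversal order")
  }
  structure(list(tree = tree, species = species, samples = samples,
                 relNe = x, NeRef = NeRef, genTime = genTime,
                 events = events),
            class = "popModel")
}

#' @export
print.popModel <- function(x, ...) {
  cat("popModel:", length(x$species), "species,",
      sum(x$samples), "haploid samples\n")
  for (s in x$species)
    cat("  ", s, ": n =", x$samples[[s]], ", Ne =",
        format(x$relNe[[s]] * x$NeRef, big.mark = ","), "\n")
  invisible(x)
}

## population membership of each species at a given divergence event:
## species descending from the merged node join one ancestral population
.speciesGroups <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  desc <- function(n) {
    if (n <= ntip) return(tree$tip.label[n])
    kids <- tree$edge[tree$edge[, 1] == n, 2]
    unlist(lapply(kids, desc))
  }
  desc(node)
}

#' Simulate a multispecies coalescent genealogy
#'
#' Samples a genealogy over all haploid samples under the neutral
#' Wright-Fisher multispecies coalescent. Within each population the
#' waiting time to the next coalescence among `j` lineages is exponential
#' with rate `choose(j, 2) / (Ne_pop / Ne_ref)`; populations merge at the
#' species divergence times. Time is measured in units of `4 * Ne_ref`
#' generations.
#'
#' @param model A [popModel()].
#' @param seed Optional integer seed (set it for reproducibility; leave
#'   `NULL` inside loops that manage their own RNG state).
#' @return A list of class `genealogy`: `ntips`, `species` (per tip),
#'   `parent` (per node, 0 for the root), `nodeTime`, `totalLength`.
#' @export
simulateGenealogy <- function(model, seed = NULL) {
  stopifnot(inherits(model, "popModel"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  ntips <- sum(model$samples)
  species <- rep(model$species, times = model$samples[model$species])
  nnode_max <- 2L * ntips - 1L
  parent <- integer(nnode_max)
  node_time <- numeric(nnode_max)
  # population assignment of active lineages
  pops <- split(seq_len(ntips), species)[unique(species)]
  relNe <- model$relNe
  next_node <- ntips + 1L
  t <- 0
  events <- model$events
  ev_i <- 1L
  repeat {
    # next divergence event time (Inf when exhausted)
    t_div <- if (!is.null(events) && ev_i <= nrow(events))
      events$time[ev_i] else Inf
    # candidate coalescence: minimum over populations
    repeat {
      waits <- vapply(names(pops), function(p) {
        j <- length(pops[[p]])
        if (j < 2L) return(Inf)
        x <- if (p %in% names(relNe)) relNe[[p]] else 1
        stats::rexp(1L, rate = choose(j, 2) / x)
      }, numeric(1))
      if (all(!is.finite(waits)) && !is.finite(t_div)) {
        if (sum(lengths(pops)) > 1L)
          stop("cannot coalesce remaining lineages")
        break
      }
      wmin <- min(waits)
      if (t + wmin < t_div) {
        p <- names(pops)[which.min(waits)]
        t <- t + wmin
        pair <- sample(pops[[p]], 2L)
        node <- next_node
        next_node <- next_node + 1L
        parent[pair] <- node
        node_time[node] <- t
        pops[[p]] <- c(setdiff(pops[[p]], pair), node)
      } else break
    }
    if (!is.finite(t_div)) break
    # merge populations at the divergence event
    t <- t_div
    grp <- .speciesGroups(model$tree, events$node[ev_i])
    anc <- paste0("anc", events$node[ev_i])
    # populations whose member lineages all descend from grp species merge
    member <- vapply(names(pops), function(p) {
      sp <- unique(species[.tipDescendants(pops[[p]], parent, ntips)])
      all(sp %in% grp)
    }, logical(1))
    merged <- unlist(pops[member], use.names = FALSE)
    pops[member] <- NULL
    pops[[anc]] <- merged
    relNe[[anc]] <- 1  # ancestral populations at reference size
    ev_i <- ev_i + 1L
  }
  nnode <- next_node - 1L
  structure(list(ntips = ntips, species = species,
                 parent = parent[seq_len(nnode)],
                 nodeTime = node_time[seq_len(nnode)],
                 totalLength = .totalLength(parent[seq_len(nnode)],
                                            node_time[seq_len(nnode)])),
            class = "genealogy")
}

## tips (sample indices) below a set of active lineage nodes
.tipDescendants <- function(nodes, parent, ntips) {
  children <- vector("list", length(parent))
  for (i in seq_along(parent)) {
    if (parent[i] > 0L)
      children[[parent[i]]] <- c(children[[parent[i]]], i)
  }
  out <- integer()
  stack <- nodes
  while (length(stack)) {
    n <- stack[[1L]]
    stack <- stack[-1L]
    if (n <= ntips) out <- c(out, n) else stack <- c(stack, children[[n]])
  }
  out
}

.totalLength <- function(parent, node_time) {
  idx <- which(parent > 0L)
  sum(node_time[parent[idx]] - node_time[idx])
}

#' @export
print.genealogy <- function(x, ...) {
  cat("genealogy:", x$ntips, "tips,",
      length(unique(x$species)), "species, TMRCA",
      round(max(x$nodeTime), 3), "coalescent units\n")
  invisible(x)
}

#' Drop mutations on a genealogy
#'
#' Places mutation counts on every branch as independent Poisson draws
#' with mean `theta/2 * branch length` (ms scaling: the expected number
#' of pairwise differences for two samples in one population is theta).
#'
#' @param g A `genealogy` from [simulateGenealogy()].
#' @param theta Population-scaled mutation rate.
#' @param seed Optional integer seed.
#' @return Integer vector of per-node mutation counts on the branch above
#'   each non-root node (0 for the root).
#' @export
dropMutations <- function(g, theta, seed = NULL) {
  stopifnot(inherits(g, "genealogy"), theta > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(g$parent)
  counts <- integer(n)
  idx <- which(g$parent > 0L)
  len <- g$nodeTime[g$parent[idx]] - g$nodeTime[idx]
  counts[idx] <- stats::rpois(length(idx), theta / 2 * len)
  counts
}

#' Stepwise copy-number states at the tips of a genealogy
#'
#' Each mutation changes the copy number by +1 or -1 with probability
#' 1/2 (stepwise mutation model, microsatellite-style). Tip copy number
#' is the root state plus the signed sum along the root-to-tip path,
#' clipped at 0.
#'
#' @param g A `genealogy`.
#' @param mutationCounts Per-node counts from [dropMutations()].
#' @param rootCN Ancestral copy number at the root (>= 1).
#' @param seed Optional integer seed.
#' @return data.frame with columns `species` and `cn`, one row per
#'   haploid sample.
#' @export
stepwiseCopyNumber <- function(g, mutationCounts, rootCN = 5L, seed = NULL) {
  stopifnot(inherits(g, "genealogy"), rootCN >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(g$parent)
  net <- vapply(seq_len(n), function(i) {
    m <- mutationCounts[i]
    if (m == 0L) 0 else sum(sample(c(-1, 1), m, replace = TRUE))
  }, numeric(1))
  # accumulate from root down: children ordered after parents by index
  state <- numeric(n)
  root <- which(g$parent == 0L)
  state[root] <- rootCN
  for (i in order(g$nodeTime, decreasing = TRUE)) {
    if (i == root) next
    state[i] <- state[g$parent[i]] + net[i]
  }
  data.frame(species = g$species,
             cn = pmax(0, state[seq_len(g$ntips)]))
}

#' Simulate replicate copy-number samples, with optional truncation
#' selection
#'
#' Runs genealogy + mutation + stepwise layers for `reps` replicates.
#' When `maxCN` is finite, any replicate containing a tip copy number
#' above `maxCN` is rejected and redrawn in full (truncation selection
#' against maladaptively high copy numbers); the acceptance rate is
#' recorded. Seeds for each attempt are derived from `seed` by a counter
#' so the accepted stream is reproducible and, when nothing is rejected,
#' identical to the unselected stream.
#'
#' @param model A [popModel()].
#' @param theta Population-scaled mutation rate.
#' @param reps Number of accepted replicates to return.
#' @param rootCN Ancestral copy number.
#' @param maxCN Truncation bound (default 12, the highest copy number
#'   observed among primates); `Inf` disables selection.
#' @param seed Integer seed.
#' @return data.frame with columns `replicate`, `species`, `cn`;
#'   attributes `acceptance` (accepted/attempted) and `attempts`.
#' @export
simulateCopyNumbers <- function(model, theta, reps = 100L, rootCN = 5L,
                                maxCN = 12, seed = 1L) {
  stopifnot(reps >= 1L)
  out <- vector("list", reps)
  attempts <- 0L
  accepted <- 0L
  counter <- 0L
  base <- as.integer(seed)
  while (accepted < reps) {
    counter <- counter + 1L
    sub_seed <- (base + 7919L * counter) %% .Machine$integer.max
    set.seed(sub_seed)
    g <- simulateGenealogy(model)
    mc <- dropMutations(g, theta)
    cn <- stepwiseCopyNumber(g, mc, rootCN = rootCN)
    attempts <- attempts + 1L
    if (any(cn$cn > maxCN)) {
      if (attempts >= 10000L && accepted / attempts < 1e-4)
        stop("truncation-selection acceptance rate below 1e-4; ",
             "check rootCN/maxCN/theta")
      next
    }
    accepted <- accepted + 1L
    cn$replicate <- accepted
    out[[accepted]] <- cn
  }
  res <- do.call(rbind, out)[, c("replicate", "species", "cn")]
  attr(res, "acceptance") <- accepted / attempts
  attr(res, "attempts") <- attempts
  res
}

#' Within- and between-species copy-number variation summaries
#'
#' Within-species variation is the sample variance of haploid copy
#' numbers per species; between-group variation is the sample variance of
#' the species mean copy numbers within each named group.
#'
#' @param samples data.frame with columns `species`, `cn` (one
#'   replicate), e.g. a subset of [simulateCopyNumbers()] output.
#' @param groups Optional named list of species vectors defining
#'   between-group comparisons (each group needs >= 2 species).
#' @param pooled When `TRUE`, between-group variation is instead the
#'   variance over all haplotypes pooled across the group's species.
#' @return List with elements `within` (named numeric) and `between`
#'   (named numeric, empty when no groups given).
#' @export
variationSummary <- function(samples, groups = NULL, pooled = FALSE) {
  stopifnot(all(c("species", "cn") %in% names(samples)))
  counts <- table(samples$species)
  if (any(counts < 2L))
    stop("every scored species needs at least 2 haplotypes")
  within <- vapply(split(samples$cn, samples$species), stats::var,
                   numeric(1))
  between <- numeric(0)
  if (!is.null(groups)) {
    between <- vapply(groups, function(sp) {
      if (length(sp) < 2L) stop("between-group comparison needs >= 2 species")
      sub <- samples[samples$species %in% sp, ]
      if (pooled) stats::var(sub$cn)
      else stats::var(vapply(split(sub$cn, sub$species)[sp], mean,
                             numeric(1)))
    }, numeric(1))
  }
  list(within = within, between = between)
}

#' Observed vs neutral copy-number variation across a theta grid
#'
#' For each scaled mutation rate, simulates the null distribution of
#' within-species and between-group copy-number variation and compares it
#' to the observed genotype table: each cell holds the ratio of observed
#' variation to the mean simulated variation (< 1 means less variation
#' than the neutral expectation) and the empirical p-value
#' `P(simulated <= observed)`.
#'
#' @param obs data.frame of observed genotypes with columns `species`,
#'   `individual`, `allele1`, `allele2` (diploid rows; expanded to
#'   haplotypes), or a pre-expanded data.frame with `species`, `cn`.
#'   May contain species absent from `model` when every group naming
#'   them supplies its own null species set.
#' @param model A [popModel()] whose sample sizes match the observed
#'   haplotype counts for the simulated species (typically the shallow
#'   reference tree the null is simulated on).
#' @param thetas Vector of theta values (grid).
#' @param reps Replicates per theta.
#' @param groups Named list of between-species comparisons. Each entry
#'   is either a character vector of species (used for both the observed
#'   statistic and its simulated null) or a list with elements `obs` and
#'   `null` naming the observed and simulated species sets separately —
#'   the setup where deep-family observed contrasts are
#'   referred to a null simulated on the shallow reference tree.
#' @param rootCN,maxCN,seed Passed to [simulateCopyNumbers()].
#' @param minHaplotypes Minimum haplotypes for a species to be scored
#'   within-species (default 6, i.e. more than 3 diploid individuals).
#' @return List of matrices `ratio` and `p` (rows comparisons, columns
#'   thetas), plus `observed` (named observed statistics).
#' @export
obsVsNullGrid <- function(obs, model, thetas, reps = 200L, groups = NULL,
                          rootCN = 5L, maxCN = 12, seed = 1L,
                          minHaplotypes = 6L) {
  hap <- expandGenotypes(obs)
  counts <- table(hap$species)
  # within-species comparisons restricted to simulated species
  scored <- intersect(names(counts)[counts >= minHaplotypes],
                      model$species)
  if (length(scored) == 0L && is.null(groups))
    stop("no species with enough haplotypes and no groups given")
  obs_groups <- lapply(groups, function(g) if (is.list(g)) g$obs else g)
  null_groups <- lapply(groups, function(g) if (is.list(g)) g$null else g)
  bad <- !vapply(null_groups, function(g) all(g %in% model$species),
                 logical(1))
  if (any(bad))
    stop("null species not in the model for group(s): ",
         paste(names(groups)[bad], collapse = ", "))
  obs_sum <- variationSummary(hap, groups = obs_groups)
  obs_stats <- c(
    if (length(scored)) stats::setNames(
      obs_sum$within[scored], paste0("within_", scored)),
    if (!is.null(groups)) stats::setNames(
      obs_sum$between, paste0("between_", names(groups))))
  comparisons <- names(obs_stats)
  ratio <- matrix(NA_real_, length(comparisons), length(thetas),
                  dimnames = list(comparisons, as.character(thetas)))
  pmat <- ratio
  for (j in seq_along(thetas)) {
    sims <- simulateCopyNumbers(model, thetas[j], reps = reps,
                                rootCN = rootCN, maxCN = maxCN,
                                seed = as.integer(seed) + 1000L * j)
    vs <- vapply(split(sims, sims$replicate), function(rep_df) {
      s <- variationSummary(rep_df, groups = null_groups)
      c(if (length(scored)) s$within[scored],
        if (!is.null(groups)) s$between)
    }, numeric(length(comparisons)))
    null_stats <- if (is.matrix(vs)) t(vs) else matrix(vs, ncol = 1L)
    colnames(null_stats) <- comparisons
    for (cmp in comparisons) {
      mu <- mean(null_stats[, cmp])
      ratio[cmp, j] <- if (mu > 0) obs_stats[[cmp]] / mu else NA_real_
      pmat[cmp, j] <- mean(null_stats[, cmp] <= obs_stats[[cmp]])
    }
  }
  list(ratio = ratio, p = pmat, observed = obs_stats)
}

#' Expand a diploid genotype table to haplotypes
#'
#' @param obs data.frame with columns `species`, `individual`, `allele1`,
#'   `allele2`; a data.frame already holding `species`, `cn` passes
#'   through unchanged.
#' @return data.frame with columns `species`, `cn`.
#' @export
expandGenotypes <- function(obs) {
  if (all(c("species", "cn") %in% names(obs)))
    return(obs[, c("species", "cn")])
  stopifnot(all(c("species", "allele1", "allele2") %in% names(obs)))
  data.frame(
    species = rep(obs$species, 2L),
    cn = c(obs$allele1, obs$allele2)
  )
}

#' Read a diploid genotype table from TSV
#'
#' @param file TSV with header `species`, `individual`, `allele1`,
#'   `allele2`.
#' @return data.frame as read.
#' @export
readGenotypeTable <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
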