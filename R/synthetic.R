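## synthetic_data: seeded generator of aligned barcode datasets with a
## known species truth, a configurable barcode gap, and injected
## discordance scenarios.
##
## Species ancestors sit at the tips of a simulated pure-birth tree,
## scaled so the SHALLOWEST species split yields the target inter-species
## p-distance in expectation (deeper pairs diverge more, as in real
## data). Individuals hang off each species ancestor on a random
## coalescent subtree whose root height is half the Jukes-Cantor time
## matching the intra-species target, so the deepest within-species pair
## hits intra_divergence in expectation. A random root sequence then
## evolves along the full grafted genealogy under a Jukes-Cantor per-site
## process, making sequences and the returned ultrametric tree mutually
## consistent. Scenario injections rewrite morphospecies labels only; the
## truth partition is never touched.

## Jukes-Cantor: expected p-distance after total time t (subst/site),
## and its inverse.
.jc_p <- function(t) 0.75 * (1 - exp(-4 * t / 3))
.jc_t <- function(p) {
  if (any(p >= 0.75)) bc_stop("p-distance target must be < 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

## Evolve a residue string along a branch of length t (JC transitions).
.jc_evolve <- function(seq_chars, t) {
  p_diff <- .jc_p(t)
  n <- length(seq_chars)
  hit <- stats::runif(n) < p_diff
  if (any(hit)) {
    cur <- seq_chars[hit]
    seq_chars[hit] <- vapply(cur, function(b)
      sample(setdiff(.BASES, b), 1L), character(1))
  }
  seq_chars
}

#' Configuration for the synthetic barcode generator
#'
#' @param n_species number of true species `K` (default 4).
#' @param samples_per_species integer (recycled) or per-species vector
#'   (default 5).
#' @param seq_length aligned sites (default 650).
#' @param intra_divergence expected within-species p-distance
#'   (default 0.01).
#' @param inter_divergence expected p-distance between the closest sister
#'   species (default 0.10; the gap ratio is inter/intra).
#' @param scenarios list of injections; each element is a list with a
#'   `type` in `CRYPTIC_SPLIT` (fields `species`: two or more species
#'   indices relabelled as one morphospecies), `LUMP` (field `species`:
#'   one species whose specimens receive two labels), `MISID` (field
#'   `rate`), `PROVISIONAL` (field `fraction` of species relabelled
#'   provisionally), `SHORT_FRAGMENT` (fields `fraction`, `length`).
#' @param reference_fraction share of specimens per species labelled
#'   `EXTERNAL` (reference library) rather than `STUDY` (default 0).
#' @param provisional_reference_fraction share of the external references
#'   given a provisional label (default 0); exercises the exclusion of
#'   provisionally named references from best-match lists. The
#'   `PROVISIONAL` scenario itself only ever relabels study specimens.
#' @param seed integer seed (mandatory).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 4L, samples_per_species = 5L,
                             seq_length = 650L, intra_divergence = 0.01,
                             inter_divergence = 0.10, scenarios = list(),
                             reference_fraction = 0,
                             provisional_reference_fraction = 0, seed) {
  if (missing(seed)) bc_stop("seed is mandatory")
  if (n_species < 1L) bc_stop("need n_species >= 1")
  samples <- rep_len(as.integer(samples_per_species), n_species)
  if (any(samples < 1L)) bc_stop("need >= 1 sample per species")
  if (!(inter_divergence > intra_divergence))
    bc_stop("inter_divergence must exceed intra_divergence")
  if (intra_divergence < 0 || inter_divergence >= 0.75)
    bc_stop("divergence targets must lie in [0, 0.75)")
  if (reference_fraction < 0 || reference_fraction > 1)
    bc_stop("reference_fraction must be in [0, 1]")
  if (provisional_reference_fraction < 0 || provisional_reference_fraction > 1)
    bc_stop("provisional_reference_fraction must be in [0, 1]")
  for (sc in scenarios)
    if (!isTRUE(sc$type %in% c("CRYPTIC_SPLIT", "LUMP", "MISID",
                               "PROVISIONAL", "SHORT_FRAGMENT")))
      bc_stop("unknown scenario type: %s", format(sc$type))
  structure(list(n_species = as.integer(n_species), samples = samples,
                 seq_length = as.integer(seq_length),
                 intra_divergence = intra_divergence,
                 inter_divergence = inter_divergence,
                 scenarios = scenarios,
                 reference_fraction = reference_fraction,
                 provisional_reference_fraction = provisional_reference_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic aligned barcode dataset
#'
#' @param config a [synthetic_config()].
#' @return List with `sequences` (named character vector), `records`
#'   (metadata data.frame), `truth` (a `partition` holding the species
#'   assignment, untouched by label injections), `ledger` (data.frame of
#'   injected scenarios with the discordance category each must produce),
#'   and `tree` (the true genealogy as an ultrametric `phylo`).
#' @export
generate_barcodes <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  K <- config$n_species
  with_seed(config$seed, {
    ## ---- species tree, scaled to the inter target ------------------
    t_intra <- .jc_t(config$intra_divergence)
    t_inter <- .jc_t(config$inter_divergence)
    if (K >= 2L) {
      sptree <- ape::rphylo(K, birth = 1, death = 0)
      depth <- ape::node.depth.edgelength(sptree)
      nh <- max(depth[seq_len(K)]) - depth[(K + 1L):(K + sptree$Nnode)]
      scale <- (t_inter / 2) / min(nh)
      sptree$edge.length <- sptree$edge.length * scale
      sptree$tip.label <- sprintf("SP%02d", seq_len(K))
    } else sptree <- NULL

    ## ---- individuals and grafted genealogy -------------------------
    ids <- character(0); species <- integer(0)
    for (k in seq_len(K)) for (j in seq_len(config$samples[k])) {
      ids <- c(ids, sprintf("SP%02d_I%02d", k, j))
      species <- c(species, k)
    }
    ## within-species coalescent subtree, root height t_intra / 2
    subtree_txt <- function(k) {
      nids <- ids[species == k]
      if (length(nids) == 1L) return(nids)
      st <- ape::rcoal(length(nids), tip.label = nids)
      depth <- max(ape::node.depth.edgelength(st))
      st$edge.length <- st$edge.length * (t_intra / 2) / depth
      sub("\\);$", ")", ape::write.tree(st))
    }
    tree <- if (K == 1L) {
      ape::read.tree(text = paste0(sub("^([^;]*);$", "\\1", subtree_txt(1L)), ";"))
    } else {
      ## shorten each species terminal branch by the subtree height so
      ## every individual still sits at the present
      term <- match(seq_len(K), sptree$edge[, 2L])
      multi <- config$samples > 1L
      if (any(sptree$edge.length[term][multi] <= t_intra / 2))
        bc_stop("species terminal branches shorter than the within-species depth; increase inter_divergence")
      txt <- ape::write.tree(sptree)
      for (k in seq_len(K)) {
        blen <- sptree$edge.length[term[k]] -
          if (multi[k]) t_intra / 2 else 0
        txt <- sub(sprintf("SP%02d:[0-9.eE+-]+", k),
                   sprintf("%s:%.12g", subtree_txt(k), blen), txt)
      }
      ape::read.tree(text = txt)
    }

    ## ---- evolve a root sequence along the genealogy ----------------
    root <- sample(.BASES, config$seq_length, replace = TRUE)
    ntot <- length(tree$tip.label)
    states <- vector("list", ntot + tree$Nnode)
    states[[ntot + 1L]] <- root
    chdepth <- ape::node.depth.edgelength(tree)[tree$edge[, 2L]]
    eord <- order(chdepth)
    for (e in eord) {
      par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      states[[ch]] <- .jc_evolve(states[[par]], tree$edge.length[e])
    }
    tipseq <- vapply(states[seq_len(ntot)], paste0, character(1), collapse = "")
    sequences <- stats::setNames(tipseq[match(ids, tree$tip.label)], ids)
    attr(sequences, "aligned_length") <- config$seq_length

    ## ---- labels, provenance, scenarios -----------------------------
    label_of <- stats::setNames(sprintf("Simulata species%02d", seq_len(K)),
                                seq_len(K))
    labels <- label_of[as.character(species)]
    provisional <- rep(FALSE, length(ids))
    provenance <- rep("STUDY", length(ids))
    if (config$reference_fraction > 0) {
      for (k in seq_len(K)) {
        kid <- which(species == k)
        nref <- floor(config$reference_fraction * length(kid))
        if (nref >= 1L) provenance[kid[seq_len(nref)]] <- "EXTERNAL"
      }
    }
    ledger <- list()
    note <- function(type, labs, detail) ledger[[length(ledger) + 1L]] <<-
      data.frame(type = type, morphospecies = paste(labs, collapse = ", "),
                 expected = switch(type, CRYPTIC_SPLIT = "SPLIT",
                                   LUMP = "LUMP", type),
                 detail = detail, stringsAsFactors = FALSE)
    for (sc in config$scenarios) {
      if (sc$type == "CRYPTIC_SPLIT") {
        sp <- as.integer(sc$species)
        if (length(sp) < 2L || any(sp > K)) bc_stop("CRYPTIC_SPLIT needs >=2 valid species")
        lab <- label_of[[as.character(sp[1L])]]
        labels[species %in% sp] <- lab
        note("CRYPTIC_SPLIT", lab,
             sprintf("species %s share one label", paste(sp, collapse = "+")))
      } else if (sc$type == "LUMP") {
        sp <- as.integer(sc$species[1L])
        if (sp > K) bc_stop("LUMP species index out of range")
        kid <- which(species == sp)
        if (length(kid) < 2L) bc_stop("LUMP needs >=2 specimens in species %d", sp)
        alt <- sprintf("Simulata pseudospecies%02d", sp)
        half <- kid[seq_len(ceiling(length(kid) / 2))]
        labels[setdiff(kid, half)] <- alt
        note("LUMP", c(label_of[[as.character(sp)]], alt),
             sprintf("species %d carries two labels", sp))
      } else if (sc$type == "MISID") {
        hit <- which(stats::runif(length(ids)) < sc$rate & provenance == "STUDY")
        for (i in hit) {
          other <- setdiff(seq_len(K), species[i])
          if (!length(other)) next
          labels[i] <- label_of[[as.character(sample(other, 1L))]]
          note("MISID", labels[i], sprintf("specimen %s mislabelled", ids[i]))
        }
      } else if (sc$type == "PROVISIONAL") {
        nprov <- ceiling(sc$fraction * K)
        if (nprov >= 1L) {
          spp <- sample(seq_len(K), min(nprov, K))
          for (sp in spp) {
            plab <- sprintf("Simulata sp. %02d", sp)
            hit <- species == sp & labels == label_of[[as.character(sp)]] &
              provenance == "STUDY"
            labels[hit] <- plab
            provisional[hit] <- TRUE
            note("PROVISIONAL", plab, sprintf("species %d provisional", sp))
          }
        }
      } else if (sc$type == "SHORT_FRAGMENT") {
        hit <- which(stats::runif(length(ids)) < sc$fraction)
        keep <- as.integer(sc$length)
        if (keep < 1L || keep > config$seq_length)
          bc_stop("SHORT_FRAGMENT length out of range")
        for (i in hit) {
          start <- sample(config$seq_length - keep + 1L, 1L)
          s <- strsplit(sequences[[i]], "")[[1L]]
          mask <- rep(TRUE, config$seq_length)
          mask[start:(start + keep - 1L)] <- FALSE
          s[mask] <- "-"
          sequences[i] <- paste0(s, collapse = "")
          note("SHORT_FRAGMENT", labels[i],
               sprintf("specimen %s masked to %d sites", ids[i], keep))
        }
      }
    }
    if (config$provisional_reference_fraction > 0) {
      ext <- which(provenance == "EXTERNAL")
      nprovref <- floor(config$provisional_reference_fraction * length(ext))
      if (nprovref >= 1L) {
        hit <- sample(ext, nprovref)
        labels[hit] <- sprintf("Simulata sp. ref%02d", species[hit])
        provisional[hit] <- TRUE
      }
    }
    records <- data.frame(specimen_id = ids, morphospecies = labels,
                          provisional = provisional, provenance = provenance,
                          taxon_class = "Simulata",
                          locality = "in silico",
                          stringsAsFactors = FALSE)
    truth <- partition(stats::setNames(sprintf("SP%02d", species), ids),
                       "truth")
    ledger_df <- if (length(ledger)) do.call(rbind, ledger) else
      data.frame(type = character(0), morphospecies = character(0),
                 expected = character(0), detail = character(0),
                 stringsAsFactors = FALSE)
    list(sequences = sequences, records = records, truth = truth,
         ledger = ledger_df, tree = tree)
  })
}

#' Realized intra/inter divergence summary of a generated dataset
#'
#' @param sequences named character vector of aligned residue strings.
#' @param truth a `partition` giving the true species assignment.
#' @param min_overlap passed to [p_distance_matrix()].
#' @return List: `max_intra_per_species` (named vector), `max_intra`,
#'   `mean_intra`, `min_inter` (`NA` for a single species), `mean_inter`,
#'   `gap_ratio` (`min_inter / max_intra`).
#' @export
calibration_report <- function(sequences, truth, min_overlap = 100L) {
  dm <- p_distance_matrix(sequences, min_overlap = min_overlap)
  grp <- truth$assignment[dm$ids]
  same <- outer(grp, grp, "==")
  ut <- upper.tri(dm$d)
  intra <- dm$d[ut & same]
  inter <- dm$d[ut & !same]
  intra <- intra[!is.na(intra)]; inter <- inter[!is.na(inter)]
  per <- vapply(split(dm$ids, grp), function(idset) {
    if (length(idset) < 2L) return(NA_real_)
    sub <- dm$d[idset, idset]
    v <- sub[upper.tri(sub)]
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
  }, numeric(1))
  max_intra <- if (length(intra)) max(intra) else NA_real_
  min_inter <- if (length(inter)) min(inter) else NA_real_
  list(max_intra_per_species = per,
       max_intra = max_intra,
       mean_intra = if (length(intra)) mean(intra) else NA_real_,
       min_inter = min_inter,
       mean_inter = if (length(inter)) mean(inter) else NA_real_,
       gap_ratio = if (!is.na(max_intra) && !is.na(min_inter) && max_intra > 0)
         min_inter / max_intra else NA_real_)
}
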