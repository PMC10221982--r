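# Gene-family evolution simulator.
#
# A single ancestral gene enters the species tree at the root and evolves
# top-down: along each species branch every live gene lineage duplicates at
# rate lambda_dup and is lost at rate lambda_loss per Myr; at a WGD placed
# on a branch every live lineage doubles, each copy surviving independently
# with the event's retention probability; and every duplication (including
# a WGD doubling that keeps both copies) is "locked" with probability p_dfd
# — the differentiation lock multiplies the loss rate of both daughters and
# their descendants by lock_loss_factor (0 = full protection) until a later
# duplication re-draws the lock. The full event history is logged so that
# inference can be scored against the truth.

#' Simulation parameters for gene-family evolution
#'
#' @param lambda_dup Duplication rate per gene lineage per Myr.
#' @param lambda_loss Loss rate per gene lineage per Myr.
#' @param p_dfd Probability that a duplication is locked (both daughters
#'   protected by functional differentiation).
#' @param lock_loss_factor Multiplier on `lambda_loss` for locked lineages
#'   (default 0: locked copies are never lost).
#' @param lock_min_age Locks are only drawn for duplications older than
#'   this age in Mya (default 0: no restriction).
#' @param wgd_events Optional WGD table (see [readWgdTable()]) with columns
#'   `name`, `branch_node_label`, `age_min`, `age_max` plus `retention_prob`
#'   and optionally `age` (defaults to the interval midpoint).
#' @param family_tag Family tag used in simulated leaf labels (default
#'   `"GUS"`).
#' @param seed Optional integer seed; fixing it makes the simulation output
#'   byte-identical across runs.
#' @return A list of class `sim_params`.
#' @export
simParams <- function(lambda_dup = 0, lambda_loss = 0, p_dfd = 0,
                      lock_loss_factor = 0, lock_min_age = 0,
                      wgd_events = NULL, family_tag = "GUS", seed = NULL) {
  stopifnot(lambda_dup >= 0, lambda_loss >= 0,
            p_dfd >= 0, p_dfd <= 1,
            lock_loss_factor >= 0, lock_min_age >= 0)
  if (!is.null(wgd_events)) {
    stopifnot(is.data.frame(wgd_events))
    if (is.null(wgd_events$retention_prob)) wgd_events$retention_prob <- 1
    stopifnot(all(wgd_events$retention_prob >= 0),
              all(wgd_events$retention_prob <= 1))
  }
  structure(list(lambda_dup = lambda_dup, lambda_loss = lambda_loss,
                 p_dfd = p_dfd, lock_loss_factor = lock_loss_factor,
                 lock_min_age = lock_min_age, wgd_events = wgd_events,
                 family_tag = family_tag, seed = seed),
            class = "sim_params")
}

#' Simulate a dated species tree
#'
#' A birth-death tree conditioned on the number of extant tips (via
#' [ape::rphylo()]), optionally rescaled to a chosen root age, with
#' generated 6-letter taxon codes as tip labels.
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth_rate,death_rate Speciation and extinction rates per lineage
#'   per Myr.
#' @param seed Optional integer seed.
#' @param root_age Optional root age in Mya; branch lengths are rescaled so
#'   the root sits at this age.
#' @param taxon_prefix 3-letter prefix for generated taxon codes (default
#'   `"Sim"`, giving `Simaaa`, `Simaab`, ...).
#' @param retries Resampling cap if tree simulation fails (default 100).
#' @return A `species_tree`.
#' @export
simulateSpeciesTree <- function(n_tips, birth_rate, death_rate = 0,
                                seed = NULL, root_age = NULL,
                                taxon_prefix = "Sim", retries = 100L) {
  stopifnot(n_tips >= 2, birth_rate > 0, death_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  phy <- NULL
  for (i in seq_len(retries)) {
    phy <- tryCatch(ape::rphylo(n_tips, birth_rate, death_rate,
                                fossils = FALSE),
                    error = function(e) NULL)
    if (!is.null(phy)) break
  }
  if (is.null(phy))
    stop("species-tree simulation failed after ", retries, " attempts",
         call. = FALSE)
  if (!is.null(root_age)) {
    depth <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length * root_age / depth
  }
  phy$tip.label <- makeTaxonCodes(n_tips, taxon_prefix)
  speciesTree(phy)
}

makeTaxonCodes <- function(n, prefix = "Sim") {
  stopifnot(grepl("^[A-Za-z]{3}$", prefix), n <= 26^3)
  grid <- expand.grid(a = letters, b = letters, c = letters,
                      stringsAsFactors = FALSE)
  codes <- paste0(prefix, grid$c, grid$b, grid$a)[seq_len(n)]
  codes
}

#' Evolve a gene family on a dated species tree
#'
#' Runs the duplication/loss/WGD/lock process described in
#' [simParams()] and returns the pruned gene tree of extant copies together
#' with the complete event log and a ground-truth table of duplication
#' events (birth-death duplications and WGD doublings that retained both
#' copies), each with the extant leaf sets of its two daughters.
#'
#' @param species_tree A `species_tree`.
#' @param params A `sim_params`.
#' @return A list of class `gene_family_sim` with elements:
#'   * `gene_tree`: a `gene_tree` of extant copies, or `NULL` if the family
#'     went extinct everywhere (with a warning);
#'   * `log`: data frame `(time, branch, kind, lineage, parent)` with kinds
#'     `DUP`, `LOSS`, `WGD_RETAIN`, `WGD_LOSE`, `LOCK`;
#'   * `truth`: data frame of duplication-type events with `event_id`,
#'     `time`, `branch_node`, `branch_label`, `kind` (`DUP`/`WGD`),
#'     `locked`, `n1`, `n2` and list-columns `leaves_1`, `leaves_2`;
#'   * `leaves`: data frame mapping leaf labels to lineage ids and taxa.
#' @export
evolveGeneFamily <- function(species_tree, params) {
  st <- species_tree
  stopifnot(inherits(st, "species_tree"), inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  ages <- st$ages
  ntip <- ape::Ntip(st)
  kids_s <- childrenList(st)
  par_s <- parentVector(st)
  root <- if (st$Nnode >= 1L) ntip + 1L else 1L
  branchLabel <- function(v) {
    if (v <= ntip) return(st$tip.label[v])
    if (!is.null(st$node.label) && nzchar(st$node.label[v - ntip]))
      return(st$node.label[v - ntip])
    paste0("node", v)
  }
  # place WGDs on branches
  branch_wgds <- vector("list", ntip + st$Nnode)
  wt <- params$wgd_events
  if (!is.null(wt) && nrow(wt)) {
    if (is.null(wt$age)) wt$age <- (wt$age_min + wt$age_max) / 2
    for (i in seq_len(nrow(wt))) {
      v <- resolveSpeciesNode(st, wt$branch_node_label[i])
      if (is.na(v))
        stop("WGD '", wt$name[i], "' refers to unknown branch label '",
             wt$branch_node_label[i], "'", call. = FALSE)
      if (v == root)
        stop("WGD '", wt$name[i], "' placed above the species root; ",
             "the simulation starts at the root", call. = FALSE)
      top <- ages[par_s[v]]
      if (!(wt$age[i] > ages[v] && wt$age[i] <= top))
        stop("WGD '", wt$name[i], "' age ", wt$age[i],
             " outside its branch interval (", ages[v], ", ", top, "]",
             call. = FALSE)
      branch_wgds[[v]] <- rbind(branch_wgds[[v]], wt[i, , drop = FALSE])
    }
  }
  S <- new.env(parent = emptyenv())
  S$lin <- 0L; S$uid <- 0L; S$eid <- 0L
  S$log <- list(); S$truth <- list(); S$leaves <- list()
  newLin <- function() { S$lin <- S$lin + 1L; S$lin }
  addLog <- function(time, v, kind, lineage, parent)
    S$log[[length(S$log) + 1L]] <-
      list(time = time, branch = branchLabel(v), kind = kind,
           lineage = lineage, parent = parent)
  collectLeaves <- function(node) {
    if (is.null(node)) return(integer(0))
    if (node$leaf) return(node$uid)
    unlist(lapply(node$children, collectLeaves))
  }
  combine2 <- function(a, b, t, eid) {
    alive <- Filter(Negate(is.null), list(a, b))
    if (!length(alive)) return(NULL)
    if (length(alive) == 1L) return(alive[[1L]])
    list(leaf = FALSE, age = t, children = alive, event = eid)
  }
  drawLock <- function(t)
    t >= params$lock_min_age && stats::runif(1L) < params$p_dfd

  enterNode <- function(v, locked, lin) {
    if (v <= ntip) {
      S$uid <- S$uid + 1L
      S$leaves[[length(S$leaves) + 1L]] <-
        list(uid = S$uid, species = v, lineage = lin)
      return(list(leaf = TRUE, age = 0, uid = S$uid))
    }
    subs <- list()
    for (ch in kids_s[[v]]) {
      # a fresh lineage id per child branch, so that a loss on one side of
      # a speciation never refers to a lineage still alive on the other
      r <- simBranch(ch, ages[v], locked, newLin())
      if (!is.null(r)) subs <- c(subs, list(r))
    }
    if (!length(subs)) return(NULL)
    if (length(subs) == 1L) return(subs[[1L]])
    list(leaf = FALSE, age = ages[v], children = subs, event = NA_integer_)
  }

  simBranch <- function(v, t, locked, lin) {
    loss_rate <- params$lambda_loss *
      (if (locked) params$lock_loss_factor else 1)
    total <- params$lambda_dup + loss_rate
    wg <- branch_wgds[[v]]
    next_wgd_i <- NA_integer_; next_wgd_age <- -Inf
    if (!is.null(wg)) {
      cand <- which(wg$age < t)
      if (length(cand)) {
        next_wgd_i <- cand[which.max(wg$age[cand])]
        next_wgd_age <- wg$age[next_wgd_i]
      }
    }
    t_bd <- if (total > 0) t - stats::rexp(1L, total) else -Inf
    if (next_wgd_age > ages[v] && next_wgd_age >= t_bd) {
      # the lineage meets a WGD before anything else happens
      w <- wg[next_wgd_i, , drop = FALSE]
      t <- next_wgd_age
      keep <- stats::runif(2L) < w$retention_prob
      S$eid <- S$eid + 1L; eid <- S$eid
      lin1 <- newLin(); lin2 <- newLin()
      addLog(t, v, if (keep[1L]) "WGD_RETAIN" else "WGD_LOSE", lin1, lin)
      addLog(t, v, if (keep[2L]) "WGD_RETAIN" else "WGD_LOSE", lin2, lin)
      if (all(keep)) {
        locked_new <- drawLock(t)
        if (locked_new) {
          addLog(t, v, "LOCK", lin1, lin)
          addLog(t, v, "LOCK", lin2, lin)
        }
        a <- simBranch(v, t, locked_new, lin1)
        b <- simBranch(v, t, locked_new, lin2)
        S$truth[[length(S$truth) + 1L]] <-
          list(event_id = eid, time = t, branch_node = v,
               branch_label = branchLabel(v), kind = "WGD",
               locked = locked_new,
               l1 = collectLeaves(a), l2 = collectLeaves(b))
        return(combine2(a, b, t, eid))
      }
      if (any(keep))
        return(simBranch(v, t, locked, if (keep[1L]) lin1 else lin2))
      return(NULL)
    }
    if (t_bd > ages[v]) {
      t <- t_bd
      if (stats::runif(1L) < params$lambda_dup / total) {
        S$eid <- S$eid + 1L; eid <- S$eid
        locked_new <- drawLock(t)
        lin1 <- newLin(); lin2 <- newLin()
        addLog(t, v, "DUP", lin1, lin)
        addLog(t, v, "DUP", lin2, lin)
        if (locked_new) {
          addLog(t, v, "LOCK", lin1, lin)
          addLog(t, v, "LOCK", lin2, lin)
        }
        a <- simBranch(v, t, locked_new, lin1)
        b <- simBranch(v, t, locked_new, lin2)
        S$truth[[length(S$truth) + 1L]] <-
          list(event_id = eid, time = t, branch_node = v,
               branch_label = branchLabel(v), kind = "DUP",
               locked = locked_new,
               l1 = collectLeaves(a), l2 = collectLeaves(b))
        return(combine2(a, b, t, eid))
      }
      addLog(t, v, "LOSS", lin, lin)
      return(NULL)
    }
    enterNode(v, locked, lin)
  }

  result <- enterNode(root, FALSE, newLin())

  # label extant copies: taxon code + tag + per-species ordinal
  leaves <- if (length(S$leaves)) {
    data.frame(uid = vapply(S$leaves, `[[`, integer(1L), "uid"),
               species = vapply(S$leaves, `[[`, integer(1L), "species"),
               lineage = vapply(S$leaves, `[[`, integer(1L), "lineage"))
  } else {
    data.frame(uid = integer(0), species = integer(0), lineage = integer(0))
  }
  leaves$taxon <- st$tip.label[leaves$species]
  leaves$label <- rep(NA_character_, nrow(leaves))
  for (tx in unique(leaves$taxon)) {
    idx <- which(leaves$taxon == tx)
    leaves$label[idx] <- paste0(tx, params$family_tag, seq_along(idx))
  }
  label_of <- stats::setNames(leaves$label, leaves$uid)

  gene_tree <- NULL
  if (is.null(result)) {
    warning("gene family went extinct in every species", call. = FALSE)
  } else {
    fmt <- function(x) sprintf("%.6f", x)
    nwk <- function(node, parent_age) {
      if (node$leaf)
        return(paste0(label_of[[as.character(node$uid)]], ":",
                      fmt(parent_age)))
      paste0("(",
             paste(vapply(node$children, nwk, character(1L),
                          parent_age = node$age), collapse = ","),
             "):", fmt(parent_age - node$age))
    }
    text <- if (result$leaf) {
      paste0("(", label_of[[as.character(result$uid)]], ":",
             fmt(ages[root]), ");")
    } else {
      paste0("(",
             paste(vapply(result$children, nwk, character(1L),
                          parent_age = result$age), collapse = ","),
             ");")
    }
    gene_tree <- geneTree(text, family_tag = params$family_tag)
  }

  log_df <- if (length(S$log)) {
    data.frame(time = vapply(S$log, `[[`, numeric(1L), "time"),
               branch = vapply(S$log, `[[`, character(1L), "branch"),
               kind = vapply(S$log, `[[`, character(1L), "kind"),
               lineage = vapply(S$log, `[[`, integer(1L), "lineage"),
               parent = vapply(S$log, `[[`, integer(1L), "parent"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(time = numeric(0), branch = character(0),
               kind = character(0), lineage = integer(0),
               parent = integer(0), stringsAsFactors = FALSE)
  }
  truth_df <- if (length(S$truth)) {
    out <- data.frame(
      event_id = vapply(S$truth, `[[`, integer(1L), "event_id"),
      time = vapply(S$truth, `[[`, numeric(1L), "time"),
      branch_node = vapply(S$truth, `[[`, integer(1L), "branch_node"),
      branch_label = vapply(S$truth, `[[`, character(1L), "branch_label"),
      kind = vapply(S$truth, `[[`, character(1L), "kind"),
      locked = vapply(S$truth, `[[`, logical(1L), "locked"),
      stringsAsFactors = FALSE)
    out$leaves_1 <- lapply(S$truth, function(r)
      unname(label_of[as.character(r$l1)]))
    out$leaves_2 <- lapply(S$truth, function(r)
      unname(label_of[as.character(r$l2)]))
    out$n1 <- lengths(out$leaves_1)
    out$n2 <- lengths(out$leaves_2)
    out[order(out$event_id), , drop = FALSE]
  } else {
    out <- data.frame(event_id = integer(0), time = numeric(0),
                      branch_node = integer(0), branch_label = character(0),
                      kind = character(0), locked = logical(0),
                      stringsAsFactors = FALSE)
    out$leaves_1 <- list(); out$leaves_2 <- list()
    out$n1 <- integer(0); out$n2 <- integer(0)
    out
  }
  structure(list(gene_tree = gene_tree, log = log_df, truth = truth_df,
                 leaves = leaves, species_tree = st, params = params),
            class = "gene_family_sim")
}

#' @export
print.gene_family_sim <- function(x, ...) {
  cat("Simulated gene family:",
      if (is.null(x$gene_tree)) 0L else ape::Ntip(x$gene_tree),
      "extant copies;", nrow(x$truth), "duplication-type events;",
      sum(x$log$kind == "LOSS"), "losses\n")
  invisible(x)
}

#' Extant copy number per species
#'
#' @param sim A `gene_family_sim`.
#' @return Named integer vector over all species-tree tips (0 where the
#'   family is absent).
#' @export
copyNumber <- function(sim) {
  stopifnot(inherits(sim, "gene_family_sim"))
  tips <- sim$species_tree$tip.label
  counts <- table(factor(sim$leaves$taxon, levels = tips))
  stats::setNames(as.integer(counts), tips)
}

#' Score inferred duplications against the simulated truth
#'
#' Matches each ground-truth duplication (birth-death or WGD doubling with
#' both copies retained) to an inferred duplication event by its pair of
#' daughter leaf sets. A truth event is *detectable* when both daughters
#' left extant descendants. DFD recall is computed over locked detectable
#' events whose carrying branch ends at or above `ancient_cutoff` — the
#' events an age-qualified classifier can possibly call ancient.
#'
#' @param sim A `gene_family_sim`.
#' @param events A classified `dfd_events` table for `sim$gene_tree`
#'   (see [classifyEvents()]).
#' @param config A `dfd_config` (for `ancient_cutoff`).
#' @return A list with counts `n_true`, `n_detectable`, `n_inferred`,
#'   `n_matched`, rates `recall` and `precision`, and the DFD-specific
#'   `dfd_denominator`, `dfd_recall` and `dfd_likely_fraction`.
#' @export
truthVsInferred <- function(sim, events, config = dfdConfig()) {
  stopifnot(inherits(sim, "gene_family_sim"))
  truth <- sim$truth
  detectable <- truth[truth$n1 > 0L & truth$n2 > 0L, , drop = FALSE]
  n_inferred <- nrow(events)
  if (is.null(sim$gene_tree) || !n_inferred || !nrow(detectable)) {
    return(list(n_true = nrow(truth), n_detectable = nrow(detectable),
                n_inferred = n_inferred, n_matched = 0L,
                recall = if (nrow(detectable)) 0 else NA_real_,
                precision = if (n_inferred) 0 else NA_real_,
                dfd_denominator = 0L, dfd_recall = NA_real_,
                dfd_likely_fraction =
                  if (n_inferred) mean(events$verdict == "DFD_LIKELY",
                                       na.rm = TRUE) else NA_real_))
  }
  gt <- sim$gene_tree
  sets <- cladeLeafSets(gt)
  kids <- childrenList(gt)
  inf_keys <- vapply(seq_len(n_inferred), function(i) {
    ch <- kids[[events$gene_node[i]]]
    pairKey(sets[[ch[1L]]], sets[[ch[2L]]])
  }, character(1L))
  true_keys <- vapply(seq_len(nrow(detectable)), function(i)
    pairKey(detectable$leaves_1[[i]], detectable$leaves_2[[i]]),
    character(1L))
  match_idx <- match(true_keys, inf_keys)
  matched <- !is.na(match_idx)
  ages <- sim$species_tree$ages
  anc <- ages[detectable$branch_node] >= config$ancient_cutoff
  dfd_den <- detectable$locked & anc
  dfd_hit <- dfd_den & matched &
    events$verdict[match_idx] %in% "DFD_LIKELY"
  dfd_hit[is.na(dfd_hit)] <- FALSE
  list(n_true = nrow(truth),
       n_detectable = nrow(detectable),
       n_inferred = n_inferred,
       n_matched = sum(matched),
       recall = mean(matched),
       precision = sum(!is.na(match(inf_keys, true_keys))) / n_inferred,
       dfd_denominator = sum(dfd_den),
       dfd_recall = if (sum(dfd_den)) sum(dfd_hit) / sum(dfd_den)
                    else NA_real_,
       dfd_likely_fraction = mean(events$verdict == "DFD_LIKELY",
                                  na.rm = TRUE))
}

# order-independent key for an unordered pair of leaf sets
pairKey <- function(a, b) {
  ka <- paste(sort(a), collapse = ",")
  kb <- paste(sort(b), collapse = ",")
  if (ka <= kb) paste(ka, kb, sep = " || ") else paste(kb, ka, sep = " || ")
}
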