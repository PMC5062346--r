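#' Simulation parameters for the codon alignment generator
#'
#' Defaults describe a mitochondrial barcode-like marker: AT-biased
#' equilibrium composition (62% AT), transition excess (kappa = 4), an
#' extra multiplier on the damage-type C-to-T and G-to-A transitions
#' (alpha = 2), a mix of invariant, group-constrained and free codon
#' sites, and strong purifying selection at free sites (nonsynonymous
#' acceptance 0.1). Deletions, when enabled, arise only on parasite
#' terminal branches, with geometric lengths and positions biased
#' towards loop columns.
#'
#' @param n_taxa Number of tips.
#' @param n_codons Codon sites per sequence.
#' @param tree Optional newick string; otherwise a Yule tree is drawn.
#' @param class_fractions Named numeric: fractions of `invariant`,
#'   `group_constrained` and `free` codon sites (sum 1).
#' @param table_id NCBI genetic code (default 5).
#' @param rate Proposal rate per nucleotide site per unit branch length.
#' @param kappa Transition/transversion proposal ratio (> 0).
#' @param alpha Extra multiplier on C-to-T and G-to-A proposals.
#' @param base_freqs Equilibrium base frequencies (A, C, G, T).
#' @param accept_nonsyn Acceptance probability for nonsynonymous changes
#'   at free sites (1 = neutral, small = purifying).
#' @param n_parasite Number of tips labelled parasitic (a clade of about
#'   this size is chosen).
#' @param deletion_rate Expected deletion events per parasite branch.
#' @param mean_deletion_length Mean deletion length in residues
#'   (geometric).
#' @param loop_columns Integer codon columns forming the deletion
#'   hotspot; default scales the canonical barcode loop intervals to
#'   `n_codons`.
#' @param loop_bias Relative weight of a loop column when placing a
#'   deletion.
#' @param seed Integer seed; every artifact records it.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_taxa = 50L, n_codons = 200L, tree = NULL,
                       class_fractions = c(invariant = 0.3,
                                           group_constrained = 0.3,
                                           free = 0.4),
                       table_id = 5L, rate = 0.05, kappa = 4, alpha = 2,
                       base_freqs = c(A = 0.30, C = 0.22, G = 0.16, T = 0.32),
                       accept_nonsyn = 0.1, n_parasite = 0L,
                       deletion_rate = 0, mean_deletion_length = 3,
                       loop_columns = NULL, loop_bias = 10, seed = 1L) {
  stopifnot(n_taxa >= 2L, n_codons >= 1L, rate >= 0, kappa > 0, alpha > 0,
            deletion_rate >= 0, mean_deletion_length >= 1)
  cf <- class_fractions[c("invariant", "group_constrained", "free")]
  if (anyNA(cf) || any(cf < 0) || abs(sum(cf) - 1) > 1e-9) {
    abort("class_fractions must be nonnegative, named and sum to 1.")
  }
  bf <- base_freqs[c("A", "C", "G", "T")]
  stopifnot(abs(sum(bf) - 1) < 1e-9, all(bf > 0))
  if (is.null(loop_columns)) loop_columns <- scale_loop_columns(n_codons)
  structure(list(n_taxa = as.integer(n_taxa), n_codons = as.integer(n_codons),
                 tree = tree, class_fractions = cf, table_id = table_id,
                 rate = rate, kappa = kappa, alpha = alpha, base_freqs = bf,
                 accept_nonsyn = accept_nonsyn,
                 n_parasite = as.integer(n_parasite),
                 deletion_rate = deletion_rate,
                 mean_deletion_length = mean_deletion_length,
                 loop_columns = as.integer(loop_columns),
                 loop_bias = loop_bias, seed = as.integer(seed)),
            class = "sim_params")
}

# Canonical loop intervals rescaled from 219 columns to n_codons.
scale_loop_columns <- function(n_codons) {
  seg <- coi_segments()
  loops <- seg[seg$type == "loop", ]
  cols <- unlist(map2(loops$start, loops$end, seq))
  unique(pmax(1L, pmin(n_codons, as.integer(round(cols * n_codons / 219)))))
}

#' Simulate a Yule tree
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed.
#' @return A newick string (tips `t1..tN`).
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  stopifnot(n_taxa >= 2L)
  tr <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  ape::write.tree(tr)
}

is_transition <- function(from, to) {
  (from %in% c("A", "G") & to %in% c("A", "G")) |
    (from %in% c("C", "T") & to %in% c("C", "T"))
}

# Tips of the clade whose size is closest to n_parasite (ties: first).
parasite_tips <- function(tree, n_parasite) {
  if (n_parasite <= 0L) return(character(0))
  n <- length(tree$tip.label)
  if (n_parasite >= n) return(tree$tip.label)
  sizes <- map_int((n + 1L):(n + tree$Nnode), function(nd) {
    length(ape::extract.clade(tree, nd)$tip.label)
  })
  best <- which.min(abs(sizes - n_parasite))
  ape::extract.clade(tree, n + best)$tip.label
}

#' Simulate a codon alignment with known ground truth
#'
#' Root codons are drawn stop-free from the equilibrium base
#' frequencies. Along each branch, single-nucleotide proposals arise at
#' the configured rate under an HKY-like scheme (target weighted by its
#' equilibrium frequency, times kappa for transitions, times alpha for
#' C-to-T and G-to-A). A proposal is accepted only if it creates no stop
#' codon and the site class permits it: invariant sites reject every
#' change; group-constrained sites reject amino acid changes that leave
#' the root residue's biochemical group; free sites accept synonymous
#' changes always and nonsynonymous ones with probability
#' `accept_nonsyn`. Every accepted event is logged, so leaves can be
#' reproduced exactly by [replay_truth()].
#'
#' @param params A [sim_params()] object.
#' @return A list with `alignment` (a `marker_alignment`, parasitic
#'   flags set from the chosen parasite clade) and `truth` (class
#'   `synthetic_truth`: site classes, root sequence, newick tree, event
#'   log, deletion log, parameters).
#' @export
simulate_alignment <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  code <- genetic_code(params$table_id)
  tb <- codon_tables(code)
  newick <- params$tree %||% simulate_tree(params$n_taxa, params$seed)
  tree <- ape::read.tree(text = newick)
  n_tip <- length(tree$tip.label)
  Lc <- params$n_codons
  bases <- c("A", "C", "G", "T")
  bf <- params$base_freqs

  out <- with_seed(params$seed, {
    classes <- sample(names(params$class_fractions), Lc, replace = TRUE,
                      prob = params$class_fractions)
    draw_codon <- function() {
      repeat {
        cd <- paste(sample(bases, 3, replace = TRUE, prob = bf), collapse = "")
        if (unname(code$codons[cd]) != "*") return(cd)
      }
    }
    root <- map_chr(seq_len(Lc), ~ draw_codon())
    root_group <- aa_group(unname(code$codons[root]))

    # proposal weights: 4x4 from-base x to-base
    W <- outer(bases, bases, function(f, t) {
      w <- bf[t] * ifelse(is_transition(f, t), params$kappa, 1)
      w * ifelse((f == "C" & t == "T") | (f == "G" & t == "A"),
                 params$alpha, 1)
    })
    dimnames(W) <- list(bases, bases)
    diag(W) <- 0

    seqs <- vector("list", n_tip + tree$Nnode)
    seqs[[n_tip + 1L]] <- root
    events <- list()
    edge_order <- reorder(tree, "cladewise")$edge
    for (e in seq_len(nrow(edge_order))) {
      parent <- edge_order[e, 1]; child <- edge_order[e, 2]
      sq <- seqs[[parent]]
      bl <- tree$edge.length[which(tree$edge[, 1] == parent &
                                     tree$edge[, 2] == child)]
      n_prop <- rpois(1, params$rate * bl * 3 * Lc)
      for (k in seq_len(n_prop)) {
        pos <- sample.int(3L * Lc, 1L)
        site <- (pos - 1L) %/% 3L + 1L
        within <- (pos - 1L) %% 3L + 1L
        if (classes[site] == "invariant") next
        cur <- sq[[site]]
        from <- substr(cur, within, within)
        to <- sample(bases, 1L, prob = W[from, ])
        cand <- cur
        substr(cand, within, within) <- to
        aa_new <- unname(code$codons[cand])
        if (aa_new == "*") next
        aa_old <- unname(code$codons[cur])
        if (aa_new != aa_old) {
          if (classes[site] == "group_constrained") {
            if (aa_group(aa_new) != root_group[site]) next
          } else if (runif(1) > params$accept_nonsyn) next
        }
        sq[[site]] <- cand
        events[[length(events) + 1L]] <-
          list(child = child, site = site, from = cur, to = cand)
      }
      seqs[[child]] <- sq
    }
    list(classes = classes, root = root, seqs = seqs, events = events)
  })

  para <- parasite_tips(tree, params$n_parasite)
  aln <- marker_alignment(
    map_chr(seq_len(n_tip), ~ paste(out$seqs[[.x]], collapse = "")),
    id = tree$tip.label,
    lineage = ifelse(tree$tip.label %in% para, "parasite_clade",
                     "free_living"),
    parasitic = tree$tip.label %in% para)
  events <- if (length(out$events)) {
    bind_rows(map(out$events, as_tibble))
  } else {
    tibble(child = integer(), site = integer(), from = character(),
           to = character())
  }
  truth <- structure(
    list(site_class = out$classes, root_seq = out$root, newick = newick,
         events = events,
         deletions = tibble(id = character(), start = integer(),
                            length = integer()),
         params = params),
    class = "synthetic_truth")
  list(alignment = aln, truth = truth)
}

#' Inject parasite-restricted deletions
#'
#' Draws deletion events on parasite terminal branches at the configured
#' rate, with geometric residue lengths and start positions biased
#' towards loop columns, and applies them as frame-preserving runs of 3k
#' gap characters. The truth log is updated so [replay_truth()] still
#' reproduces the alignment.
#'
#' @param aln A `marker_alignment` from [simulate_alignment()].
#' @param truth The matching `synthetic_truth`.
#' @param params The [sim_params()] used (deletion fields are read from
#'   here).
#' @return A list with the gapped `alignment` and updated `truth`.
#' @export
inject_deletions <- function(aln, truth, params) {
  Lc <- params$n_codons
  if (params$deletion_rate == 0 || params$n_parasite == 0L) {
    return(list(alignment = aln, truth = truth))
  }
  w <- rep(1, Lc)
  w[params$loop_columns] <- params$loop_bias
  res <- with_seed(params$seed + 1L, {
    dels <- list()
    seqs <- setNames(aln$seq, aln$id)
    for (id in aln$id[which(aln$parasitic)]) {
      n_ev <- rpois(1, params$deletion_rate)
      taken <- rep(FALSE, Lc)
      for (k in seq_len(n_ev)) {
        ok <- FALSE
        for (try in 1:100) {
          len <- 1L + rgeom(1, 1 / params$mean_deletion_length)
          if (len >= Lc) next
          start <- sample.int(Lc - len + 1L, 1L,
                              prob = w[seq_len(Lc - len + 1L)])
          span <- start:(start + len - 1L)
          if (any(taken[span])) next
          taken[span] <- TRUE
          s <- seqs[[id]]
          nt_start <- 3L * (start - 1L) + 1L
          substr(s, nt_start, nt_start + 3L * len - 1L) <-
            strrep("-", 3L * len)
          seqs[[id]] <- s
          dels[[length(dels) + 1L]] <-
            list(id = id, start = start, length = len)
          ok <- TRUE
          break
        }
        if (!ok) warn("Could not place a deletion after 100 attempts.")
      }
    }
    list(seqs = seqs, dels = dels)
  })
  new_aln <- marker_alignment(unname(res$seqs[aln$id]), id = aln$id,
                              lineage = aln$lineage,
                              parasitic = aln$parasitic)
  truth$deletions <- if (length(res$dels)) {
    bind_rows(map(res$dels, as_tibble))
  } else truth$deletions
  list(alignment = new_aln, truth = truth)
}

#' Replay a truth log into leaf sequences
#'
#' Event-sourcing check for the simulator: starting from the root codon
#' sequence, applies every logged substitution along the tree and every
#' logged deletion, and returns the resulting leaf sequences. These must
#' equal the emitted alignment exactly.
#'
#' @param truth A `synthetic_truth`.
#' @return Tibble with `id`, `seq`.
#' @export
replay_truth <- function(truth) {
  tree <- ape::read.tree(text = truth$newick)
  n_tip <- length(tree$tip.label)
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[n_tip + 1L]] <- truth$root_seq
  edge_order <- reorder(tree, "cladewise")$edge
  ev <- truth$events
  for (e in seq_len(nrow(edge_order))) {
    parent <- edge_order[e, 1]; child <- edge_order[e, 2]
    sq <- seqs[[parent]]
    branch_ev <- ev[ev$child == child, , drop = FALSE]
    for (k in seq_len(nrow(branch_ev))) {
      stopifnot(sq[[branch_ev$site[[k]]]] == branch_ev$from[[k]])
      sq[[branch_ev$site[[k]]]] <- branch_ev$to[[k]]
    }
    seqs[[child]] <- sq
  }
  out <- tibble(id = tree$tip.label,
                seq = map_chr(seq_len(n_tip), ~ paste(seqs[[.x]],
                                                      collapse = "")))
  for (k in seq_len(nrow(truth$deletions))) {
    d <- truth$deletions[k, ]
    i <- which(out$id == d$id)
    nt_start <- 3L * (d$start - 1L) + 1L
    s <- out$seq[[i]]
    substr(s, nt_start, nt_start + 3L * d$length - 1L) <-
      strrep("-", 3L * d$length)
    out$seq[[i]] <- s
  }
  out
}
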