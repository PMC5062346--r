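#' Assemble a run configuration
#'
#' Collects every tunable of the analysis chain (filter, collapse,
#' translate, profile, structure, stats) with the package defaults:
#' entropy threshold 0.5 nats, consensus threshold 0.995, ligand
#' distance threshold 5 Angstrom, invertebrate mitochondrial code,
#' barcode full length 658 nt.
#'
#' @param fasta Path to the gapped FASTA input.
#' @param metadata Optional metadata TSV path.
#' @param pdb Optional reference PDB path (enables the structure stage).
#' @param segments A segment tibble or TSV path; default
#'   [coi_segments()].
#' @param out_dir Output directory for TSV/JSON reports.
#' @param table_id,frame Genetic code and reading frame.
#' @param max_ambiguous_fraction,required_length Quality filter.
#' @param entropy_threshold,consensus_threshold Site classification.
#' @param chain,offset,ligand_names,ligand_threshold Structure stage.
#' @param max_pairs,seed dN/dS pair subsampling.
#' @param sim A [sim_params()] object for [run_simulate()]; default uses
#'   `seed`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(fasta = NULL, metadata = NULL, pdb = NULL,
                       segments = coi_segments(), out_dir = tempdir(),
                       table_id = 5L, frame = "auto",
                       max_ambiguous_fraction = 0.01, required_length = NULL,
                       entropy_threshold = 0.5, consensus_threshold = 0.995,
                       chain = "A", offset = 17L,
                       ligand_names = .DEFAULT_LIGANDS, ligand_threshold = 5,
                       max_pairs = 500L, seed = 1L, sim = NULL) {
  if (is.character(segments)) segments <- read_segments(segments)
  structure(list(fasta = fasta, metadata = metadata, pdb = pdb,
                 segments = segments, out_dir = out_dir, table_id = table_id,
                 frame = frame,
                 max_ambiguous_fraction = max_ambiguous_fraction,
                 required_length = required_length,
                 entropy_threshold = entropy_threshold,
                 consensus_threshold = consensus_threshold,
                 chain = chain, offset = offset, ligand_names = ligand_names,
                 ligand_threshold = ligand_threshold, max_pairs = max_pairs,
                 seed = as.integer(seed),
                 sim = sim %||% sim_params(seed = seed)),
            class = "run_config")
}

flatten_profile <- function(profile) {
  profile |>
    mutate(groups = map_chr(.data$groups, paste, collapse = ","),
           freqs = map_chr(.data$freqs, function(f) {
             paste0(names(f), ":", signif(f, 6), collapse = ",")
           })) |>
    as_tibble()
}

#' Run the profiling stage of the pipeline
#'
#' Filter by quality, collapse haplotypes, translate, profile every
#' column, detect deletions, and (when a PDB is configured) annotate
#' ligand proximity. Writes `site_profile.tsv`,
#' `nucleotide_composition.tsv`, `aa_composition.tsv` and
#' `deletions.tsv` under `out_dir` and logs the record-count funnel.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `alignment` (collapsed), `raln`,
#'   `profile`, `deletions`, `composition`, `aa_comp`, `haplotype_map`,
#'   `funnel` (record counts at each stage) and the written `paths`.
#' @export
run_profile <- function(config) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)))
    })
  }
  aln <- stage("read", read_marker_fasta(config$fasta, config$metadata))
  n_in <- nrow(aln)
  aln_f <- stage("filter", filter_quality(aln, config$max_ambiguous_fraction,
                                          config$required_length))
  coll <- stage("collapse", collapse_haplotypes(aln_f))
  aln_h <- coll$alignment
  code <- genetic_code(config$table_id)
  raln <- stage("translate", translate_alignment(aln_h, code, config$frame))
  profile <- stage("profile",
                   profile_alignment(raln, config$segments,
                                     config$entropy_threshold,
                                     config$consensus_threshold))
  if (!is.null(config$pdb)) {
    st <- stage("structure", load_structure(config$pdb, config$chain,
                                            config$ligand_names))
    profile <- flag_proximal_sites(profile, st, config$offset,
                                   config$ligand_threshold)
  }
  dels <- stage("deletions", detect_deletions(raln))
  comp <- stage("composition",
                nucleotide_composition(aln_h, attr(raln, "frame_offset")))
  aac <- stage("composition", aa_composition(raln))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(profile = file.path(config$out_dir, "site_profile.tsv"),
             composition = file.path(config$out_dir,
                                     "nucleotide_composition.tsv"),
             aa = file.path(config$out_dir, "aa_composition.tsv"),
             deletions = file.path(config$out_dir, "deletions.tsv"))
  readr::write_tsv(flatten_profile(profile), paths[["profile"]])
  readr::write_tsv(comp, paths[["composition"]])
  readr::write_tsv(aac, paths[["aa"]])
  readr::write_tsv(dels$events, paths[["deletions"]])
  funnel <- tibble(stage = c("input", "quality_filtered", "haplotypes"),
                   records = c(n_in, nrow(aln_f), nrow(aln_h)))
  message("Filter funnel: ", paste(funnel$stage, funnel$records,
                                   sep = "=", collapse = " -> "))
  invisible(list(alignment = aln_h, raln = raln, profile = profile,
                 deletions = dels, composition = comp, aa_comp = aac,
                 haplotype_map = coll$haplotype_map, funnel = funnel,
                 paths = paths))
}

safe_g_test <- function(tab, label) {
  res <- tryCatch(g_test(tab), error = function(e) conditionMessage(e))
  if (is.character(res)) {
    list(test = label, error = res, table = tab)
  } else {
    list(test = label, statistic = res$statistic, df = res$df,
         p = res$p.value, correction = res$correction, table = res$table)
  }
}

#' Run the statistics stage of the pipeline
#'
#' Computes the loop/helix enrichment G-tests (conserved sites, variable
#' sites, most-variable sites with entropy > 1.1), the parasite-by-
#' deletion association G-test, the codon-wise dN/dS profile, the
#' normalized substitution matrix, and — when the metadata contains two
#' or more lineages — a Wilcoxon rank-sum comparison of per-codon dN/dS
#' between the two largest lineages. Every test record carries its
#' contingency table or sample sizes. Degenerate tables are reported
#' with an error message, not raised.
#'
#' @param config A [run_config()].
#' @param profile_run The result of [run_profile()].
#' @return Invisibly, a list of result records; also written as
#'   `stats.json` under `out_dir`.
#' @export
run_stats <- function(config, profile_run) {
  profile <- profile_run$profile
  aln <- profile_run$alignment
  results <- list(
    conserved_by_segment = safe_g_test(
      class_by_segment_table(profile, "conserved"),
      "conserved sites: helix vs loop"),
    variable_by_segment = safe_g_test(
      class_by_segment_table(profile, "variable"),
      "variable sites: helix vs loop"),
    high_entropy_by_segment = safe_g_test(
      class_by_segment_table(profile,
                             function(p) !is.na(p$entropy) & p$entropy > 1.1),
      "entropy > 1.1 sites: helix vs loop")
  )
  # parasite x deletion association over collapsed records
  if (any(!is.na(aln$parasitic))) {
    per_seq <- profile_run$deletions$per_sequence
    has_del <- per_seq$deleted_residues[match(aln$id, per_seq$id)] > 0
    known <- !is.na(aln$parasitic)
    tab <- table(factor(ifelse(aln$parasitic[known], "parasite",
                               "free_living"),
                        c("parasite", "free_living")),
                 factor(ifelse(has_del[known], "deletion", "no_deletion"),
                        c("deletion", "no_deletion")))
    results$parasite_deletion <- safe_g_test(
      matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab)),
      "parasitic lifestyle vs deletion")
  }
  dnds <- codon_site_dnds(aln, genetic_code(config$table_id),
                          attr(profile_run$raln, "frame_offset"),
                          config$max_pairs, seed = config$seed)
  results$dnds_median <- list(test = "median codon-wise dN/dS",
                              value = median(dnds$dnds, na.rm = TRUE),
                              n_codons = nrow(dnds))
  subst <- tryCatch(substitution_count_matrix(aln),
                    error = function(e) conditionMessage(e))
  results$substitution_matrix <- if (is.character(subst)) {
    list(test = "substitution matrix", error = subst)
  } else {
    list(test = "substitution matrix", matrix = unclass(subst),
         n_events = attr(subst, "n_events"))
  }
  lin <- aln$lineage[!is.na(aln$lineage)]
  if (length(unique(lin)) >= 2L) {
    top2 <- names(sort(table(lin), decreasing = TRUE))[1:2]
    sub_dnds <- map(top2, function(g) {
      sub <- aln[which(aln$lineage == g), , drop = FALSE]
      sub <- structure(sub, class = class(aln),
                       alignment_length = attr(aln, "alignment_length"))
      if (nrow(sub) < 2L) return(NULL)
      codon_site_dnds(sub, genetic_code(config$table_id),
                      attr(profile_run$raln, "frame_offset"),
                      config$max_pairs, seed = config$seed)$dnds
    })
    if (!any(map_int(sub_dnds, length) == 0)) {
      x <- sub_dnds[[1]][!is.na(sub_dnds[[1]])]
      y <- sub_dnds[[2]][!is.na(sub_dnds[[2]])]
      if (length(x) && length(y)) {
        w <- wilcoxon_rank_sum(x, y)
        results$dnds_wilcoxon <- list(
          test = paste0("dN/dS: ", top2[1], " vs ", top2[2]),
          statistic = w$statistic, p = w$p.value,
          n_x = w$n_x, n_y = w$n_y, correction = w$correction)
      }
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(results, file.path(config$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(as_tibble(dnds),
                   file.path(config$out_dir, "codon_dnds.tsv"))
  invisible(c(results, list(dnds_profile = dnds)))
}

#' Run the simulator and write a consumable bundle
#'
#' Simulates a codon alignment with ground truth (plus parasite
#' deletions when configured), then writes gapped FASTA, metadata TSV,
#' newick tree and truth JSON under `out_dir`. The bundle is directly
#' consumable by [run_profile()] via the returned paths.
#'
#' @param config A [run_config()]; simulation settings come from
#'   `config$sim`.
#' @return Invisibly, a list with `alignment`, `truth` and `paths`
#'   (fasta, metadata, newick, truth).
#' @export
run_simulate <- function(config) {
  params <- config$sim
  sim <- simulate_alignment(params)
  sim <- inject_deletions(sim$alignment, sim$truth, params)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(config$out_dir, "simulated.fasta"),
             metadata = file.path(config$out_dir, "simulated_metadata.tsv"),
             newick = file.path(config$out_dir, "simulated.nwk"),
             truth = file.path(config$out_dir, "simulated_truth.json"))
  write_marker_fasta(sim$alignment, paths[["fasta"]])
  readr::write_tsv(tibble(id = sim$alignment$id,
                          lineage = sim$alignment$lineage,
                          parasitic = as.integer(sim$alignment$parasitic)),
                   paths[["metadata"]])
  writeLines(sim$truth$newick, paths[["newick"]])
  truth_json <- list(site_class = sim$truth$site_class,
                     root_seq = sim$truth$root_seq,
                     newick = sim$truth$newick,
                     events = sim$truth$events,
                     deletions = sim$truth$deletions,
                     seed = params$seed)
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(list(alignment = sim$alignment, truth = sim$truth,
                 paths = paths))
}
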