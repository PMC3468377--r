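## Pipeline orchestration: a single entry point running the stages in
## dependency order with a structured config, stderr logging and
## deterministic report files. The companion command-line wrapper
## (exec/srnapipe) is a thin optparse shim over run_pipeline().

#' Default pipeline configuration
#'
#' @return nested list: `seed`, `log_level`, `paths` (inputs; filled by the
#'   simulate stage when absent), `scenario` (synthetic-data parameters,
#'   see [scenario()]), `discovery` (see [discovery_config()]), `targets`
#'   (`max_mismatch`, `min_ratio`), `conservation` (`max_mm`, `mfei_min`).
#' @export
default_config <- function() {
  list(seed = 1L,
       log_level = "info",
       paths = list(genome = NULL, annotation = NULL, reads = NULL,
                    refs = NULL, transcripts = NULL, foreign_genome = NULL),
       scenario = list(),
       discovery = discovery_config(),
       targets = list(max_mismatch = 3L, min_ratio = 0.75),
       conservation = list(max_mm = 4L, mfei_min = 0.85))
}

pipe_log <- function(cfg, level, fmt, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a pipeline configuration
#'
#' Checks threshold ranges and the existence of every referenced input
#' file; stops with the offending field or path named.
#'
#' @param config configuration list (merged over [default_config()]).
#' @param require_paths character vector of `paths` entries that must exist
#'   for the requested stages.
#' @return the merged, validated configuration (invisibly usable).
#' @export
validate_config <- function(config, require_paths = character(0)) {
  cfg <- utils::modifyList(default_config(), config)
  if (!is.numeric(cfg$discovery$mfei_min) || cfg$discovery$mfei_min <= 0)
    stop("invalid config: discovery$mfei_min must be > 0")
  if (cfg$discovery$mature_len_min > cfg$discovery$mature_len_max)
    stop("invalid config: discovery$mature_len_min > mature_len_max")
  er <- cfg$scenario$error_rate %||% 0.005
  if (er < 0 || er >= 1)
    stop("invalid config: scenario$error_rate must be in [0, 1)")
  if (!is.numeric(cfg$targets$min_ratio) || cfg$targets$min_ratio < 0)
    stop("invalid config: targets$min_ratio must be >= 0")
  for (p in require_paths) {
    v <- cfg$paths[[p]]
    if (is.null(v)) stop(sprintf("missing input: paths$%s is not set", p))
    for (f in unlist(v))
      if (!file.exists(f)) stop(sprintf("missing input: %s (paths$%s)", f, p))
  }
  cfg
}

write_gff3_precursors <- function(novel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(novel) > 0L) {
    lines <- sprintf(
      "%s\tsrnapipe\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      novel$chrom, novel$precursor_start, novel$precursor_end, novel$strand,
      novel$id, novel$id)
    writeLines(lines, con)
  }
  invisible(path)
}

write_structure_report <- function(novel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(novel))) {
    writeLines(c(sprintf(">%s %s:%d-%d(%s) MFE=%.2f MFEI=%.3f",
                         novel$id[i], novel$chrom[i],
                         novel$precursor_start[i], novel$precursor_end[i],
                         novel$strand[i], novel$mfe[i], novel$mfei[i]),
                 novel$precursor[i], novel$structure[i]), con)
  }
  invisible(path)
}

stage_simulate <- function(cfg, out) {
  sim_dir <- file.path(out, "sim")
  dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)
  scn <- do.call(scenario, utils::modifyList(list(seed = cfg$seed),
                                             cfg$scenario))
  built <- build_genome(scn)
  libs <- simulate_reads(scn, built)

  Biostrings::writeXStringSet(built$genome, file.path(sim_dir, "genome.fasta"))
  rtracklayer::export(built$gene_models,
                      file.path(sim_dir, "annotation.gff3"), format = "gff3")
  reads_paths <- list()
  for (l in names(libs)) {
    p <- file.path(sim_dir, sprintf("reads_%s.fasta", l))
    write_collapsed_fasta(libs[[l]], p)
    reads_paths[[l]] <- p
  }
  ref_paths <- list()
  for (cat in names(built$refs)) {
    p <- file.path(sim_dir, sprintf("ref_%s.fasta", cat))
    write_fasta(built$refs[[cat]], p)
    ref_paths[[cat]] <- p
  }
  tt <- make_target_transcripts(scn, stats::setNames(built$truth$mature,
                                                     built$truth$id))
  write_fasta(tt$transcripts, file.path(sim_dir, "transcripts.fasta"))
  write_tsv_report(tt$truth, file.path(sim_dir, "target_truth.tsv"))
  write_tsv_report(built$truth, file.path(sim_dir, "truth.tsv"))

  ## foreign genome for the conservation stage: an unrelated background with
  ## a handful of planted precursor copies
  set.seed(cfg$seed + 3L)
  fg <- strsplit(random_seq(50000L), "")[[1]]
  n_plant <- min(5L, nrow(built$truth))
  if (n_plant > 0L) {
    at <- 5000L + (seq_len(n_plant) - 1L) * 9000L
    for (i in seq_len(n_plant)) {
      prec <- rna_to_dna(built$truth$precursor[i])
      fg[at[i]:(at[i] + nchar(prec) - 1L)] <- strsplit(prec, "")[[1]]
    }
  }
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(fchr1 = paste(fg, collapse = ""))),
    file.path(sim_dir, "foreign_genome.fasta"))

  cfg$paths <- utils::modifyList(cfg$paths, list(
    genome = file.path(sim_dir, "genome.fasta"),
    annotation = file.path(sim_dir, "annotation.gff3"),
    reads = reads_paths, refs = ref_paths,
    transcripts = file.path(sim_dir, "transcripts.fasta"),
    foreign_genome = file.path(sim_dir, "foreign_genome.fasta")))
  pipe_log(cfg, "info", "simulate: %d hairpins planted, %d librar%s",
           nrow(built$truth), length(libs),
           if (length(libs) == 1) "y" else "ies")
  cfg
}

load_inputs <- function(cfg, what) {
  inp <- list()
  if ("genome" %in% what) inp$genome <- read_genome(cfg$paths$genome)
  if ("annotation" %in% what)
    inp$gene_models <- read_gff3(cfg$paths$annotation)
  if ("reads" %in% what)
    inp$libs <- lapply(stats::setNames(nm = names(cfg$paths$reads)),
                       function(l) read_collapsed_fasta(cfg$paths$reads[[l]], l))
  if ("refs" %in% what)
    inp$refs <- lapply(cfg$paths$refs, read_fasta)
  if ("transcripts" %in% what)
    inp$transcripts <- read_fasta(cfg$paths$transcripts)
  if ("foreign_genome" %in% what)
    inp$foreign <- read_genome(cfg$paths$foreign_genome)
  inp
}

#' Run the small-RNA analysis pipeline
#'
#' Subcommands: `simulate` (generate the synthetic study into `out/sim`),
#' `profile` (length distributions), `classify` (annotation-category
#' summary), `known` (conserved-miRNA quantification), `discover` (novel
#' miRNAs), `targets` (target prediction for discovered miRNAs),
#' `conserve` (cross-species scan of discovered miRNAs), `all` (everything
#' in dependency order). Reports are TSV files under `out/reports`; a
#' machine-readable manifest with the full config snapshot and seed is
#' written to `out/manifest.json`. Given identical inputs and seed, two
#' runs produce byte-identical reports.
#'
#' @param subcommand one of simulate, profile, classify, known, discover,
#'   targets, conserve, all.
#' @param config configuration list or path to a YAML file (merged over
#'   [default_config()]).
#' @param out output directory (created if needed).
#' @param seed overrides `config$seed` when non-NULL.
#' @return (invisibly) a list of the stage results.
#' @export
run_pipeline <- function(subcommand = "all", config = list(), out = "srnapipe_out",
                         seed = NULL) {
  sub_ok <- c("simulate", "profile", "classify", "known", "discover",
              "targets", "conserve", "all")
  if (!subcommand %in% sub_ok)
    stop(sprintf("unknown subcommand '%s'", subcommand))
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(file.path(out, "reports"), recursive = TRUE, showWarnings = FALSE)
  rep_dir <- file.path(out, "reports")
  results <- list()

  stages <- if (subcommand == "all")
    c("simulate", "profile", "classify", "known", "discover", "targets",
      "conserve") else subcommand

  if ("simulate" %in% stages) {
    cfg <- stage_simulate(cfg, out)
  }

  needs <- setdiff(stages, "simulate")
  if (length(needs) > 0L) {
    req <- c("genome", "annotation", "reads", "refs")
    if ("targets" %in% needs) req <- c(req, "transcripts")
    if ("conserve" %in% needs) req <- c(req, "foreign_genome")
    cfg <- validate_config(cfg, require_paths = intersect(
      req, c("genome", "annotation", "reads", "refs", "transcripts",
             "foreign_genome")))
    inp <- load_inputs(cfg, c("genome", "annotation", "reads", "refs",
                              if ("targets" %in% needs) "transcripts",
                              if ("conserve" %in% needs) "foreign_genome"))
    ref_map <- c(mature = "known_mature", star = "known_star", rrna = "rrna",
                 trna = "trna", snrna = "snrna", snorna = "snorna",
                 sirna = "sirna")
    refs_for_ann <- lapply(ref_map, function(k) inp$refs[[k]] %||% character(0))
    ann <- annotation_set(refs_for_ann, gene_models = inp$gene_models)
  }

  if ("profile" %in% stages) {
    prof <- do.call(rbind, lapply(names(inp$libs), function(l) {
      d <- length_distribution(inp$libs[[l]])
      cbind(library = l, d)
    }))
    write_tsv_report(prof, file.path(rep_dir, "length_dist.tsv"))
    results$profile <- prof
    pipe_log(cfg, "info", "profile: written length_dist.tsv")
  }

  hits_cache <- list()
  get_hits <- function(l) {
    if (is.null(hits_cache[[l]]))
      hits_cache[[l]] <<- map_reads(inp$libs[[l]], inp$genome,
                                    cfg$discovery$max_mismatch)
    hits_cache[[l]]
  }

  if ("classify" %in% stages) {
    summ <- do.call(rbind, lapply(names(inp$libs), function(l) {
      cbind(library = l,
            summarize_classification(inp$libs[[l]], ann, get_hits(l)))
    }))
    write_tsv_report(summ, file.path(rep_dir, "table1_summary.tsv"))
    results$classify <- summ
    pipe_log(cfg, "info", "classify: written table1_summary.tsv")
  }

  if ("known" %in% stages) {
    known_ref <- data.frame(name = names(inp$refs$known_mature),
                            mature = unname(inp$refs$known_mature),
                            stringsAsFactors = FALSE)
    ks <- lapply(names(inp$libs), function(l)
      identify_conserved(inp$libs[[l]], known_ref))
    names(ks) <- names(inp$libs)
    tab <- if (length(ks) >= 2L) {
      cmp <- compare_libraries(ks[[1]], ks[[2]])
      names(cmp) <- sub("_a$", paste0("_", names(ks)[1]), names(cmp))
      names(cmp) <- sub("_b$", paste0("_", names(ks)[2]), names(cmp))
      cmp
    } else {
      ks[[1]]
    }
    write_tsv_report(tab, file.path(rep_dir, "known_mirnas.tsv"))
    results$known <- tab
    pipe_log(cfg, "info", "known: %d conserved miRNA(s) reported", nrow(tab))
  }

  novel_all <- NULL
  if ("discover" %in% stages) {
    novel_list <- lapply(names(inp$libs), function(l) {
      lib <- inp$libs[[l]]
      cls <- classify_reads(lib, ann, get_hits(l))
      keep <- cls %in% c("intron", "other sRNAs")
      flib <- read_library(lib$reads$sequence[keep], lib$reads$count[keep],
                           lib$label)
      nv <- discover(flib, inp$genome, inp$gene_models, cfg$discovery)
      if (nrow(nv) > 0L) cbind(library = l, nv) else NULL
    })
    novel_all <- do.call(rbind, novel_list)
    if (is.null(novel_all)) {
      novel_all <- data.frame(
        library = character(), id = character(), mature = character(),
        length = integer(), count = integer(), star = character(),
        star_count = integer(), chrom = character(),
        precursor_start = integer(), precursor_end = integer(),
        strand = character(), precursor = character(),
        structure = character(), mfe = numeric(), mfei = numeric(),
        context = character(), family = integer(), stringsAsFactors = FALSE)
    } else {
      novel_all$id <- sprintf("nmiR-%02d", seq_len(nrow(novel_all)))
      novel_all$family <- group_families(novel_all$mature)
    }
    write_tsv_report(
      novel_all[, c("id", "library", "mature", "length", "count",
                    "star", "star_count", "chrom", "precursor_start",
                    "precursor_end", "strand", "context", "family",
                    "mfe", "mfei")],
      file.path(rep_dir, "novel_mirnas.tsv"))
    write_structure_report(novel_all, file.path(rep_dir,
                                                "precursor_structures.txt"))
    write_gff3_precursors(novel_all, file.path(rep_dir, "precursors.gff3"))
    results$discover <- novel_all
    pipe_log(cfg, "info", "discover: %d novel miRNA locus/loci", nrow(novel_all))
  }

  if ("targets" %in% stages) {
    if (is.null(novel_all))
      stop("targets stage requires the discover stage in the same run")
    tg <- list()
    for (i in seq_len(nrow(novel_all))) {
      p <- predict_targets(novel_all$mature[i], inp$transcripts,
                           cfg$targets$max_mismatch, cfg$targets$min_ratio)
      if (nrow(p) > 0L)
        tg[[length(tg) + 1L]] <- cbind(mirna = novel_all$id[i], p)
    }
    tg <- if (length(tg)) do.call(rbind, tg) else
      data.frame(mirna = character(), transcript = character(),
                 start = integer(), end = integer(), mismatches = integer(),
                 wobbles = integer(), ratio = numeric(),
                 strict_pass = logical(), stringsAsFactors = FALSE)
    write_tsv_report(tg, file.path(rep_dir, "targets.tsv"))
    results$targets <- tg
    pipe_log(cfg, "info", "targets: %d prediction(s)", nrow(tg))
  }

  if ("conserve" %in% stages) {
    if (is.null(novel_all))
      stop("conserve stage requires the discover stage in the same run")
    cons <- scan_conservation(
      stats::setNames(novel_all$mature, novel_all$id), inp$foreign,
      species = "foreign", max_mm = cfg$conservation$max_mm,
      mfei_min = cfg$conservation$mfei_min)
    write_tsv_report(cons, file.path(rep_dir, "conservation.tsv"))
    results$conserve <- cons
    pipe_log(cfg, "info", "conserve: %d hit(s), %d conserved",
             nrow(cons), sum(cons$conserved))
  }

  ## manifest paths are stored relative to the output directory so that two
  ## runs of the same config into different directories stay comparable
  cfg_manifest <- cfg
  cfg_manifest$paths <- lapply(cfg$paths, function(v) {
    if (is.null(v)) return(NULL)
    lapply_chr <- function(x) sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])",
                                                   "\\\\\\1", out), "/?"),
                                  "", x)
    if (is.list(v)) lapply(v, lapply_chr) else lapply_chr(v)
  })
  manifest <- list(package = "srnapipe",
                   version = as.character(utils::packageVersion("srnapipe")),
                   subcommand = subcommand, seed = cfg$seed,
                   config = cfg_manifest)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(results)
}
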