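#' Build a run configuration
#'
#' Precedence: arguments given here override values read from
#' \code{config_file} (YAML), which override the defaults.
#'
#' @param mode One of "simulate", "scan", "annotate", "context", "stats",
#'   "all".
#' @param out_dir Output directory.
#' @param seed Master seed; every stochastic stage derives its sub-seeds
#'   from it.
#' @param config_file Optional YAML file of overrides.
#' @param ... Further fields: simulate parameters (n_arms, arm_length,
#'   n_insertions, n_families, gc), input paths (genome_fasta,
#'   library_fasta, library_segments, compartments_bed, genes_gff3),
#'   thresholds / scan parameter overrides (lists), window size.
#' @return Named list, class \code{ltr_config}.
#' @export
run_config <- function(mode = "all", out_dir = "ltrscape_out", seed = 1L,
                       config_file = NULL, ...) {
  cfg <- list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
              n_arms = 2L, arm_length = 1500000L, n_insertions = 200L,
              n_families = 8L, gc = 0.45,
              genome_fasta = NULL, library_fasta = NULL,
              library_segments = NULL, compartments_bed = NULL,
              genes_gff3 = NULL,
              thresholds = list(), scan = list(), plan = list(),
              pe_size = 3e6, window = 50000L)
  if (!is.null(config_file)) {
    fromfile <- yaml::read_yaml(config_file)
    cfg[names(fromfile)] <- fromfile
  }
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg$mode <- match.arg(cfg$mode,
                        c("simulate", "scan", "annotate", "context", "stats", "all"))
  structure(cfg, class = "ltr_config")
}

# Hash of the scientific configuration (the output location does not alter
# results, so it is excluded: identical runs hash identically anywhere).
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the pipeline
#'
#' Stages run in dependency order: simulate (or load inputs), scan,
#' annotate, context, stats. Every emitted table carries a header with the
#' package version, the configuration hash and the seed; a manifest records
#' per-stage counts. Reruns with an identical configuration give
#' byte-identical outputs.
#'
#' @param config \code{\link{run_config}}.
#' @return Invisibly, a list with the in-memory results (sim, candidates,
#'   copies, map, tables, stats) and \code{paths} of the written artifacts.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log_lines <- c(file_header(config$seed, hash))
  stage <- function(msg) log_lines <<- c(log_lines, paste0("stage: ", msg))
  paths <- character(0)
  mode <- config$mode
  want <- function(s) mode == "all" || mode == s

  sim <- NULL; genome <- NULL; library <- NULL
  compartments <- NULL; genes <- NULL; exons <- NULL

  if (want("simulate")) {
    stage("simulate")
    library <- build_family_library(config$n_families, gc = config$gc,
                                    seed = derive_seed(config$seed, 1))
    bps <- default_blueprints(config$n_arms, config$arm_length,
                              seed = derive_seed(config$seed, 2))
    plans <- do.call(sample_insertion_plans,
                     c(list(blueprints = bps, library = library,
                            n = config$n_insertions,
                            seed = derive_seed(config$seed, 3)),
                       if (length(config$plan))
                         list(params = do.call(plan_params, config$plan))))
    sim <- synthesize_genome(bps, library, plans,
                             seed = derive_seed(config$seed, 4), gc = config$gc)
    sp <- write_sim(sim, config$out_dir)
    paths <- c(paths, sp)
    genome <- sim$genome
    compartments <- sim$compartments
    genes <- sim$genes; exons <- sim$exons
    log_lines <- c(log_lines, paste0("count: planted=", nrow(sim$truth)))
    if (mode == "simulate") {
      writeLines(c(log_lines), file.path(config$out_dir, "run.log"))
      return(invisible(list(sim = sim, paths = paths)))
    }
  }

  if (is.null(genome)) {
    if (is.null(config$genome_fasta) || !file.exists(config$genome_fasta))
      stop("genome FASTA missing: ", config$genome_fasta)
    if (is.null(config$library_fasta) || !file.exists(config$library_fasta))
      stop("library FASTA missing: ", config$library_fasta)
    genome <- read_genome_fasta(config$genome_fasta)
    library <- read_family_library(config$library_fasta, config$library_segments)
    if (!is.null(config$compartments_bed))
      compartments <- read_compartments_bed(config$compartments_bed)
    if (!is.null(config$genes_gff3)) {
      gg <- read_genes_gff3(config$genes_gff3)
      genes <- gg$genes; exons <- gg$exons
    }
  }

  params <- do.call(scan_params, config$scan)
  th <- do.call(annotation_thresholds, config$thresholds)

  stage("scan")
  candidates <- scan_genome(library, genome, params)
  log_lines <- c(log_lines, paste0("count: candidates=", length(candidates)))

  stage("annotate")
  copies <- annotate_copies(candidates, library, genome, th, params)
  cnt <- attr(copies, "counts")
  log_lines <- c(log_lines,
                 paste0("count: ", names(cnt), "=", cnt))
  p <- file.path(config$out_dir, "copies.tsv")
  write_tsv(format_copies_table(copies), p, config$seed, hash)
  paths <- c(paths, copies = p)

  map <- NULL; tables <- NULL; assoc <- NULL
  if (!is.null(compartments)) {
    stage("context")
    map <- derive_pericentromeric_euchromatin(compartment_map(compartments),
                                              pe_size = config$pe_size)
    copies <- assign_compartment(copies, map)
    copies <- cluster_insertions(copies, th$cluster_distance)
    if (!is.null(genes)) {
      npe <- copies[!is.na(copies$compartment) & copies$compartment == "NPE", ,
                    drop = FALSE]
      assoc <- associate_genes(npe, genes, exons, th$gene_flank)
      p <- file.path(config$out_dir, "gene_associations.tsv")
      write_tsv(assoc, p, config$seed, hash)
      paths <- c(paths, associations = p)
    }
    tables <- summarize_tables(copies, map, genes)
    for (nm in names(tables)) {
      if (is.null(tables[[nm]])) next
      p <- file.path(config$out_dir, paste0("table_", nm, ".tsv"))
      write_tsv(tables[[nm]], p, config$seed, hash)
      paths <- c(paths, p)
    }
    p <- file.path(config$out_dir, "copies_context.tsv")
    write_tsv(format_copies_table(copies), p, config$seed, hash)
    paths <- c(paths, copies_context = p)
  }

  stats <- NULL
  if (mode %in% c("stats", "all") && !is.null(map)) {
    stage("stats")
    stats <- list()
    het_n <- sum(copies$compartment %in% c("PH", "DIH", "CIH"), na.rm = TRUE)
    eu_n <- sum(copies$compartment %in% c("PE", "NPE"), na.rm = TRUE)
    het_mb <- sum(subset_len(map, c("PH", "DIH", "CIH"))) / 1e6
    eu_mb <- sum(subset_len(map, c("PE", "NPE"))) / 1e6
    if (het_n + eu_n > 0 && het_mb > 0 && eu_mb > 0) {
      g <- chisq_gof_region(het_n, eu_n, het_mb, eu_mb)
      stats$het_enrichment <- list(test = "gof_chisq",
                                   observed = g$observed,
                                   statistic = g$statistic, df = g$df,
                                   p.value = g$p.value)
    }
    hist_res <- divergence_histogram(copies)
    stats$divergence_headline <- hist_res$headline
    age <- tryCatch(condition_ratio_by_age(copies), error = function(e) NULL)
    if (!is.null(age))
      stats$condition_by_age <- list(test = "chisq_2x2",
                                     table = as.vector(age$table),
                                     statistic = age$statistic,
                                     p.value = age$p.value)
    jsonlite::write_json(stats, file.path(config$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, stats = file.path(config$out_dir, "stats.json"))
  }

  manifest <- list(version = as.character(utils::packageVersion("ltrscape")),
                   seed = config$seed, config = hash,
                   counts = as.list(attr(copies, "counts")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))

  invisible(list(sim = sim, candidates = candidates, copies = copies,
                 map = map, tables = tables, associations = assoc,
                 stats = stats, paths = paths))
}

subset_len <- function(map, labels) {
  d <- map[map$label %in% labels, , drop = FALSE]
  if (nrow(d) == 0) return(0)
  d$end - d$start + 1
}

# Copies table in the supplementary-table dialect: divergence in percent to
# one decimal ("ND" when undetermined), SV string per the dialect.
format_copies_table <- function(copies) {
  d <- copies
  d$divergence_pct <- ifelse(is.na(d$divergence), "ND",
                             sprintf("%.1f", 100 * d$divergence))
  d$divergence <- NULL
  d
}

#' Import a census table in the supplementary-dataset dialect
#'
#' Reads a tab-separated export with the columns of the published
#' per-insertion dataset: lineage, family, scaffold, scaffold coordinates,
#' chromosome, chromosome coordinates, cytological band, condition,
#' divergence (%, "ND"/"n. d." when undetermined) and the SV annotation
#' string ("del120(5'), ins45"; "No"; "ND").
#'
#' @param path TSV path.
#' @return data.frame of copies in the internal dialect (divergence as a
#'   fraction; parsed SV events in the \code{sv_events} list-column;
#'   per-row n_del/n_ins/n_dup counts).
#' @export
import_dataset_s1 <- function(path) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  check.names = FALSE)
  cn <- tolower(names(d))
  pick <- function(key, alt = NULL, idx = NULL) {
    k <- which(cn %in% c(key, alt))
    if (length(k) > 0) return(d[[k[1]]])
    if (!is.null(idx) && ncol(d) >= idx) return(d[[idx]])
    NULL
  }
  out <- data.frame(
    lineage = pick("lineage", idx = 1),
    family = pick("family", idx = 2),
    arm = pick("chr", "chromosome", idx = 6),
    start = as.integer(pick("start", "chr_start", idx = 7)),
    end = as.integer(pick("end", "chr_end", idx = 8)),
    condition = tolower(pick("condition", idx = 10)),
    stringsAsFactors = FALSE)
  out$condition[out$condition == "solo-ltr"] <- "solo-LTR"
  div <- as.character(pick("div", "divergence", idx = 11))
  div[div %in% c("ND", "n. d.", "n.d.", "nd", "")] <- NA
  out$divergence <- suppressWarnings(as.numeric(div)) / 100
  sv_raw <- as.character(pick("sv", idx = 12))
  events <- lapply(sv_raw, function(s) {
    tryCatch(parse_sv_string(s), warning = function(w) {
      warning("SV undetermined for one row: ", conditionMessage(w))
      NULL
    })
  })
  out$sv <- sv_raw
  out$sv_events <- I(events)
  out$n_del <- vapply(events, function(e) if (is.null(e)) NA_integer_ else
    sum(e$type == "del"), integer(1))
  out$n_ins <- vapply(events, function(e) if (is.null(e)) NA_integer_ else
    sum(e$type == "ins"), integer(1))
  out$n_dup <- vapply(events, function(e) if (is.null(e)) NA_integer_ else
    sum(e$type == "dup"), integer(1))
  out$id <- sprintf("S1_%04d", seq_len(nrow(out)))
  out
}
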