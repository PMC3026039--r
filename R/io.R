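file_header <- function(seed = NULL, config_hash = NULL) {
  v <- as.character(utils::packageVersion("ltrscape"))
  h <- paste0("# ltrscape ", v)
  if (!is.null(seed)) h <- paste0(h, "; seed=", seed)
  if (!is.null(config_hash)) h <- paste0(h, "; config=", config_hash)
  h
}

#' Write a genome as FASTA
#' @param genome Named character vector of arm sequences.
#' @param path Output path.
#' @param width Line width.
#' @export
write_genome_fasta <- function(genome, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    n <- nchar(s)
    starts <- seq(1, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, n)), con)
  }
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA path.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*", "", names(x))
  out
}

#' Write compartments as BED (0-based half-open, label in column 4)
#' @param compartments data.frame(arm, start, end, label), 1-based inclusive.
#' @param path Output path.
#' @export
write_compartments_bed <- function(compartments, path) {
  d <- data.frame(chrom = compartments$arm,
                  start = compartments$start - 1L,
                  end = compartments$end,
                  name = compartments$label)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a compartment BED into 1-based inclusive intervals
#' @param path BED path.
#' @export
read_compartments_bed <- function(path) {
  d <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  data.frame(arm = d[[1]], start = d[[2]] + 1L, end = d[[3]],
             label = d[[4]], stringsAsFactors = FALSE)
}

#' Write gene models as GFF3 (gene/mRNA/exon, 1-based inclusive)
#' @param genes data.frame(arm, gene_id, start, end, strand).
#' @param exons data.frame(arm, gene_id, start, end).
#' @param path Output path.
#' @export
write_genes_gff3 <- function(genes, exons, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(sprintf("%s\tltrscape\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$arm, g$start, g$end, g$strand, g$gene_id), con)
    mid <- paste0(g$gene_id, ".t1")
    writeLines(sprintf("%s\tltrscape\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$arm, g$start, g$end, g$strand, mid, g$gene_id), con)
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      writeLines(sprintf("%s\tltrscape\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         g$arm, ex$start[j], ex$end[j], g$strand, mid, j, mid), con)
    }
  }
  invisible(path)
}

#' Read gene models from GFF3
#' @param path GFF3 path.
#' @return list(genes, exons).
#' @export
read_genes_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0)
    return(list(genes = data.frame(arm = character(0), gene_id = character(0),
                                   start = integer(0), end = integer(0),
                                   strand = character(0)),
                exons = data.frame(arm = character(0), gene_id = character(0),
                                   start = integer(0), end = integer(0))))
  f <- strsplit(lines, "\t", fixed = TRUE)
  d <- data.frame(arm = vapply(f, `[[`, "", 1),
                  type = vapply(f, `[[`, "", 3),
                  start = as.integer(vapply(f, `[[`, "", 4)),
                  end = as.integer(vapply(f, `[[`, "", 5)),
                  strand = vapply(f, `[[`, "", 7),
                  attr = vapply(f, `[[`, "", 9),
                  stringsAsFactors = FALSE)
  get_attr <- function(s, key) sub(paste0(".*", key, "=([^;]+).*"), "\\1", s)
  genes <- d[d$type == "gene", ]
  genes <- data.frame(arm = genes$arm, gene_id = get_attr(genes$attr, "ID"),
                      start = genes$start, end = genes$end,
                      strand = genes$strand, stringsAsFactors = FALSE)
  ex <- d[d$type == "exon", ]
  exons <- data.frame(arm = ex$arm,
                      gene_id = sub("\\.t1$", "", get_attr(ex$attr, "Parent")),
                      start = ex$start, end = ex$end, stringsAsFactors = FALSE)
  list(genes = genes, exons = exons)
}

#' Write a tab-separated table with a provenance header
#' @param d data.frame.
#' @param path Output path.
#' @param seed,config_hash Recorded in the header comment.
#' @export
write_tsv <- function(d, path, seed = NULL, config_hash = NULL) {
  con <- file(path, "w")
  writeLines(file_header(seed, config_hash), con)
  close(con)
  suppressWarnings(write.table(d, path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(path)
}

#' Read a tab-separated table written by \code{\link{write_tsv}}
#' @param path File path.
#' @export
read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a family library as FASTA plus a segmentation table
#' @param library \code{ltr_library}.
#' @param fasta_path,segments_path Output paths.
#' @export
write_family_library <- function(library, fasta_path, segments_path) {
  cons <- vapply(library, family_consensus, character(1))
  names(cons) <- names(library)
  write_genome_fasta(cons, fasta_path)
  seg <- do.call(rbind, lapply(library, function(f) {
    data.frame(name = f$name, lineage = f$lineage,
               ltr5_end = nchar(f$ltr5),
               internal_end = nchar(f$ltr5) + nchar(f$internal),
               total = nchar(family_consensus(f)), stringsAsFactors = FALSE)
  }))
  write_tsv(seg, segments_path)
  invisible(fasta_path)
}

#' Read a family library from FASTA plus a segmentation table
#' @param fasta_path,segments_path Input paths.
#' @return \code{ltr_library}.
#' @export
read_family_library <- function(fasta_path, segments_path) {
  cons <- read_genome_fasta(fasta_path)
  seg <- read_tsv(segments_path)
  fams <- lapply(seq_len(nrow(seg)), function(i) {
    s <- cons[[seg$name[i]]]
    structure(list(name = seg$name[i], lineage = seg$lineage[i],
                   ltr5 = substr(s, 1, seg$ltr5_end[i]),
                   internal = substr(s, seg$ltr5_end[i] + 1, seg$internal_end[i]),
                   ltr3 = substr(s, seg$internal_end[i] + 1, seg$total[i])),
              class = "ltr_family")
  })
  names(fams) <- seg$name
  structure(fams, class = "ltr_library")
}

#' Write all artifacts of a simulation
#' @param sim \code{ltr_sim} from \code{\link{synthesize_genome}}.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             compartments = file.path(dir, "compartments.bed"),
             genes = file.path(dir, "genes.gff3"),
             truth = file.path(dir, "truth.tsv"),
             library_fasta = file.path(dir, "library.fa"),
             library_segments = file.path(dir, "library_segments.tsv"))
  write_genome_fasta(sim$genome, paths["genome"])
  write_compartments_bed(sim$compartments, paths["compartments"])
  if (!is.null(sim$genes) && nrow(sim$genes) > 0)
    write_genes_gff3(sim$genes, sim$exons, paths["genes"])
  write_tsv(sim$truth, paths["truth"], seed = sim$seed)
  write_family_library(sim$library, paths["library_fasta"],
                       paths["library_segments"])
  invisible(paths)
}
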