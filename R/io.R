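#' Read per-SNP allele counts from TSV or VCF
#'
#' Two input formats are supported. A four-column tab-separated table
#' (`chrom pos ref_count alt_count`, with header) is read directly. A
#' VCFv4.2 file must carry a per-sample `AD` (allele depth) FORMAT field;
#' only biallelic SNP records are used — multiallelic or indel records are
#' skipped and their number reported in the `n_skipped` attribute.
#' Positions must be strictly increasing within each chromosome.
#'
#' @param path Input file; `.vcf` (optionally gzipped) is parsed as VCF,
#'   anything else as TSV.
#' @param sample For VCF input, the sample column to read (default: first).
#' @return Allele-count tibble: `sample_id`, `chrom`, `pos`, `ref_count`,
#'   `alt_count`.
#' @export
read_allele_counts <- function(path, sample = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    out <- read_allele_counts_vcf(path, sample)
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE,
                           progress = FALSE)
    need <- c("chrom", "pos", "ref_count", "alt_count")
    if (!all(need %in% names(tab))) {
      abort(paste0("TSV must have columns: ", paste(need, collapse = ", ")))
    }
    out <- tibble(sample_id = sample %||% "sample",
                  chrom = as.character(tab$chrom),
                  pos = as.integer(tab$pos),
                  ref_count = as.integer(tab$ref_count),
                  alt_count = as.integer(tab$alt_count))
    attr(out, "n_skipped") <- 0L
  }
  bad <- out %>% group_by(chrom) %>%
    summarise(unsorted = is.unsorted(pos, strictly = TRUE),
              .groups = "drop")
  if (any(bad$unsorted)) {
    abort("positions must be strictly increasing within each chromosome")
  }
  out
}

read_allele_counts_vcf <- function(path, sample = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  biallelic_snp <- !is.na(alt) & !grepl(",", alt) &
    nchar(ref) == 1 & nchar(alt) == 1
  n_skipped <- sum(!biallelic_snp)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || nrow(ad) == 0) abort("VCF lacks a per-sample AD field")
  sample <- sample %||% colnames(ad)[1]
  if (!sample %in% colnames(ad)) {
    abort(paste0("sample not found in VCF: ", sample))
  }
  adv <- ad[biallelic_snp, sample]
  parts <- strsplit(adv, ",", fixed = TRUE)
  if (any(lengths(parts) < 2)) abort("malformed AD field")
  out <- tibble(
    sample_id = sample,
    chrom = as.character(fix[biallelic_snp, "CHROM"]),
    pos = as.integer(fix[biallelic_snp, "POS"]),
    ref_count = as.integer(vapply(parts, `[`, "", 1)),
    alt_count = as.integer(vapply(parts, `[`, "", 2))
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write allele counts as TSV or minimal VCF
#'
#' The TSV layout is `chrom pos ref_count alt_count`. The VCF layout is a
#' minimal VCFv4.2 with placeholder alleles and a single sample column
#' carrying the `AD` FORMAT field, sufficient to round-trip the counts.
#'
#' @param counts Allele-count tibble for one sample.
#' @param path Output file.
#' @param format `"tsv"` or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(counts, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(select(counts, chrom, pos, ref_count, alt_count), path,
                     progress = FALSE)
  } else {
    sample <- unique(counts$sample_id) %||% "sample"
    stopifnot(length(sample) == 1)
    header <- c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
      paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
             sample))
    body <- sprintf("%s\t%d\t.\tA\tT\t.\tPASS\t.\tAD\t%d,%d",
                    counts$chrom, counts$pos, counts$ref_count,
                    counts$alt_count)
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Write crossover calls as BED-like TSV
#'
#' One row per call with a 0-based half-open breakpoint interval
#' `[left_pos - 1, right_pos)`, sorted by chromosome, start and sample:
#' columns `chrom start end sample left_class right_class n_undet`.
#'
#' @param calls A `co_calls` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_crossovers <- function(calls, path) {
  bed <- calls %>%
    mutate(start = left_pos - 1L, end = right_pos) %>%
    select(chrom, start, end, sample = sample_id,
           left_class, right_class, n_undet = n_undetermined_spanned) %>%
    arrange(chrom, start, sample)
  readr::write_tsv(bed, path, progress = FALSE)
  invisible(path)
}

#' Read crossover calls written by [write_crossovers()]
#' @param path BED-like TSV file.
#' @return A `co_calls`-shaped tibble (1-based `left_pos`/`right_pos`).
#' @export
read_crossovers <- function(path) {
  bed <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  out <- tibble(sample_id = as.character(bed$sample),
                chrom = as.character(bed$chrom),
                left_pos = as.integer(bed$start + 1L),
                right_pos = as.integer(bed$end),
                left_class = bed$left_class,
                right_class = bed$right_class,
                n_undetermined_spanned = as.integer(bed$n_undet))
  class(out) <- c("co_calls", class(out))
  out
}

#' Write simulated crossover truth as BED-like TSV
#'
#' @param truth A `meiosis_truth` tibble.
#' @param path Output file; rows are `chrom start end phase` with the
#'   0-based single-bp interval of each crossover.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  rows <- purrr::pmap(list(truth$chrom, truth$start_phase, truth$co_pos_bp),
                      function(cn, ph, pos) {
    if (!length(pos)) return(NULL)
    tibble(chrom = cn, start = pos - 1L, end = pos, phase = ph)
  })
  readr::write_tsv(bind_rows(rows), path, progress = FALSE)
  invisible(path)
}

#' Read and write tetrad and pollen tables
#'
#' Tetrad CSV: `tetrad_id` plus logical columns `s1_m1 ... s4_m3` (spore x
#' marker presence). Pollen CSV: `pollen_id, mA, mB`.
#'
#' @param x Table to write.
#' @param path CSV file.
#' @return The tibble (readers) or `path` invisibly (writers).
#' @export
read_tetrads <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (cl in grep("^s[1-4]_m", names(out), value = TRUE)) {
    out[[cl]] <- as.logical(out[[cl]])
  }
  out
}

#' @rdname read_tetrads
#' @export
write_tetrads <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_tetrads
#' @export
read_pollen <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out$mA <- as.logical(out$mA); out$mB <- as.logical(out$mB)
  out
}

#' @rdname read_tetrads
#' @export
write_pollen <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Read and write 16-bit grayscale spot images
#'
#' Images are stored as 16-bit grayscale TIFF; the ground-truth centers of a
#' synthetic image can be saved alongside as a JSON sidecar.
#'
#' @param image Integer matrix in `[0, 65535]`.
#' @param path TIFF file.
#' @return [read_spot_image()] returns an integer matrix.
#' @export
write_spot_image <- function(image, path) {
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_spot_image
#' @export
read_spot_image <- function(path) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
}

#' @rdname write_spot_image
#' @param truth A `spot_truth` object from [render_spot_image()].
#' @export
write_spot_truth <- function(truth, path) {
  write_spot_image(truth$image, path)
  sidecar <- paste0(sub("\\.tiff?$", "", path), "_centers.json")
  jsonlite::write_json(
    list(centers = truth$centers,
         amplitude = truth$amplitude, background = truth$background,
         sigma_px = truth$sigma_px, noise_sd = truth$noise_sd),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' A flat YAML file of analysis parameters (bin size, thresholds, genome
#' file, seed, output directory). Values are returned as a named list with
#' defaults filled in; every referenced file must exist.
#'
#' @param path YAML file.
#' @return Named list of parameters.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(bin_size = 100L, min_tail = 50L, hom_max = 0.05,
                   het_min = 0.45, min_reads = 1L, seed = 1L)
  cfg <- utils::modifyList(defaults, cfg)
  for (key in c("genome", "counts", "manifest")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      abort(paste0("configured file does not exist: ", cfg[[key]]))
    }
  }
  cfg
}
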