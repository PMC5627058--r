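#' Configuration for the synthetic MeRIP-seq data generator
#'
#' Bundles every tunable of the generator with validated defaults. The
#' defaults describe a two-tissue experiment in which most peaks are shared
#' ("common") and a minority are tissue-private, IP coverage is enriched
#' over input at true peaks, and the methylation consensus GGACU (DNA
#' GGACT) is planted at most true sites.
#'
#' @param n_genes number of genes (one transcript per gene).
#' @param utr5_len_range,cds_len_range,utr3_len_range integer length-2
#'   vectors, nt ranges the segment lengths are drawn from uniformly. The
#'   defaults straddle the 100-nt UTR and 200-nt CDS topology thresholds so
#'   that the short-UTR and short-CDS edge rules are exercised.
#' @param frac_lncrna proportion of genes emitted as single-exon lncRNAs
#'   (no CDS).
#' @param n_common_peaks,n_specA_peaks,n_specB_peaks numbers of truth peaks
#'   present in both tissues, only tissue A, and only tissue B.
#' @param peak_width truth peak width, nt.
#' @param enrichment_fold mean IP/input coverage ratio inside a true peak
#'   (>= 1; 1 gives a null dataset).
#' @param base_depth mean input read count per 100-nt window.
#' @param dispersion negative-binomial size parameter for window counts
#'   (larger is closer to Poisson). The default (100) adds mild
#'   extra-Poisson noise (about 1% extra squared coefficient of variation
#'   at the default depth): the generator's job is to emulate the
#'   statistical structure the downstream window enrichment test assumes,
#'   i.e. near-Poisson within-library counting noise. Smaller values
#'   inject the stronger overdispersion seen in real coverage and are
#'   useful for robustness studies (exact conditional tests are known to
#'   become anti-conservative there).
#' @param motif 5-mer planted at truth-peak centres (DNA alphabet).
#' @param motif_plant_rate probability a truth peak gets the motif planted.
#' @param read_len simulated read length, nt.
#' @param seed integer seed; every generator function derives its RNG
#'   stream from it, so identical configs give byte-identical outputs.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 300L,
                       utr5_len_range = c(30L, 300L),
                       cds_len_range = c(120L, 1800L),
                       utr3_len_range = c(50L, 600L),
                       frac_lncrna = 0.1,
                       n_common_peaks = 150L,
                       n_specA_peaks = 25L,
                       n_specB_peaks = 25L,
                       peak_width = 100L,
                       enrichment_fold = 8,
                       base_depth = 50,
                       dispersion = 100,
                       motif = "GGACT",
                       motif_plant_rate = 0.8,
                       read_len = 100L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              utr5_len_range = as.integer(utr5_len_range),
              cds_len_range = as.integer(cds_len_range),
              utr3_len_range = as.integer(utr3_len_range),
              frac_lncrna = frac_lncrna,
              n_common_peaks = as.integer(n_common_peaks),
              n_specA_peaks = as.integer(n_specA_peaks),
              n_specB_peaks = as.integer(n_specB_peaks),
              peak_width = as.integer(peak_width),
              enrichment_fold = enrichment_fold,
              base_depth = base_depth,
              dispersion = dispersion,
              motif = toupper(motif),
              motif_plant_rate = motif_plant_rate,
              read_len = as.integer(read_len),
              seed = as.integer(seed))
  counts <- c(cfg$n_genes, cfg$n_common_peaks, cfg$n_specA_peaks,
              cfg$n_specB_peaks, cfg$peak_width, cfg$read_len)
  if (any(counts < 0L)) stop("counts must be >= 0")
  if (cfg$enrichment_fold < 1) stop("enrichment_fold must be >= 1")
  if (cfg$frac_lncrna < 0 || cfg$frac_lncrna > 1 ||
      cfg$motif_plant_rate < 0 || cfg$motif_plant_rate > 1)
    stop("proportions must lie in [0, 1]")
  ranges <- list(cfg$utr5_len_range, cfg$cds_len_range, cfg$utr3_len_range)
  if (any(vapply(ranges, function(r)
    length(r) != 2L || r[1] > r[2] || r[1] < 1L, TRUE)))
    stop("length ranges must be increasing pairs of positive integers")
  if (!grepl("^[ACGT]+$", cfg$motif)) stop("motif must be an ACGT string")
  class(cfg) <- "sim_config"
  cfg
}

# deterministic per-stage RNG: each generator stage draws from its own
# stream derived from the config seed, so stages are individually and
# jointly reproducible
with_sim_seed <- function(config, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((config$seed + offset) %% .Machine$integer.max)
  expr
}

random_dna <- function(n) {
  vapply(n, function(len)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

#' Generate a synthetic transcript annotation with sequences
#'
#' One transcript per gene (the analysis downstream uses the longest
#' transcript per gene; the simulation emits it directly). Coding genes get
#' a 5'UTR/CDS/3'UTR split with the CDS length forced to a multiple of 3;
#' lncRNA genes have no CDS. Sequences are uniform-random ACGT.
#'
#' @param config a [sim_config()].
#' @return list with `annotation` (data.frame: `gene_id`, `transcript_id`,
#'   `biotype`, `length`, `utr5_len`, `cds_len`, `utr3_len`) and
#'   `sequences` (named character vector keyed by `transcript_id`).
#' @export
sim_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (n == 0L) {
    return(list(annotation = data.frame(gene_id = character(0),
                                        transcript_id = character(0),
                                        biotype = character(0),
                                        length = integer(0),
                                        utr5_len = integer(0),
                                        cds_len = integer(0),
                                        utr3_len = integer(0),
                                        stringsAsFactors = FALSE),
                sequences = setNames(character(0), character(0))))
  }
  with_sim_seed(config, 101L, {
    gene_id <- sprintf("gene%04d", seq_len(n))
    transcript_id <- sprintf("tx%04d", seq_len(n))
    biotype <- ifelse(runif(n) < config$frac_lncrna, "lncRNA", "coding")
    draw <- function(r) sample(seq(r[1], r[2]), n, replace = TRUE)
    u5 <- draw(config$utr5_len_range)
    cds <- draw(config$cds_len_range)
    cds <- pmax(3L, (cds %/% 3L) * 3L)  # codon multiple
    u3 <- draw(config$utr3_len_range)
    len <- u5 + cds + u3
    coding <- biotype == "coding"
    ann <- data.frame(gene_id = gene_id, transcript_id = transcript_id,
                      biotype = biotype, length = len,
                      utr5_len = ifelse(coding, u5, NA_integer_),
                      cds_len = ifelse(coding, cds, NA_integer_),
                      utr3_len = ifelse(coding, u3, NA_integer_),
                      stringsAsFactors = FALSE)
    seqs <- setNames(random_dna(len), transcript_id)
    list(annotation = ann, sequences = seqs)
  })
}

#' Plant ground-truth m6A peaks into a synthetic annotation
#'
#' Places `n_common_peaks` peaks active in both tissues and
#' `n_specA_peaks`/`n_specB_peaks` tissue-private peaks at random positions
#' on randomly chosen transcripts, never overlapping one another on a
#' transcript and never crossing transcript ends. With probability
#' `motif_plant_rate` the configured motif is written into the transcript
#' sequence at the peak centre.
#'
#' @param config a [sim_config()].
#' @param annotation result of [sim_annotation()].
#' @return list with `truth` (data.frame: `gene_id`, `transcript_id`,
#'   `start`, `end` 0-based half-open, `tissues` one of `"A"`, `"B"`,
#'   `"A,B"`, `planted_fold`, `has_motif`) and `sequences` (the input
#'   sequences with motifs written in).
#' @export
sim_plant_truth <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  ann <- annotation$annotation
  seqs <- annotation$sequences
  n_peaks <- config$n_common_peaks + config$n_specA_peaks + config$n_specB_peaks
  w <- config$peak_width
  if (n_peaks == 0L) {
    empty <- data.frame(gene_id = character(0), transcript_id = character(0),
                        start = integer(0), end = integer(0),
                        tissues = character(0), planted_fold = numeric(0),
                        has_motif = logical(0), stringsAsFactors = FALSE)
    return(list(truth = empty, sequences = seqs))
  }
  eligible <- ann[ann$length >= w, ]
  if (n_peaks > 0L && nrow(eligible) == 0L)
    stop("annotation too small to place the requested truth peaks")
  with_sim_seed(config, 202L, {
    tissues <- rep(c("A,B", "A", "B"),
                   c(config$n_common_peaks, config$n_specA_peaks,
                     config$n_specB_peaks))
    tissues <- sample(tissues)  # shuffle so placement is not tissue-ordered
    placed <- vector("list", n_peaks)
    occupied <- lapply(setNames(seq_len(nrow(eligible)),
                                eligible$transcript_id),
                       function(i) IRanges::IRanges())
    for (i in seq_len(n_peaks)) {
      done <- FALSE
      for (attempt in seq_len(200L)) {
        j <- sample.int(nrow(eligible), 1L)
        tx <- eligible$transcript_id[j]
        start <- sample.int(eligible$length[j] - w + 1L, 1L) - 1L
        cand <- IRanges::IRanges(start + 1L, start + w)
        if (length(IRanges::findOverlaps(cand, occupied[[tx]])) == 0L) {
          occupied[[tx]] <- c(occupied[[tx]], cand)
          placed[[i]] <- data.frame(gene_id = eligible$gene_id[j],
                                    transcript_id = tx,
                                    start = start, end = start + w,
                                    stringsAsFactors = FALSE)
          done <- TRUE
          break
        }
      }
      if (!done) stop("could not place truth peak ", i,
                      ": annotation too crowded")
    }
    truth <- do.call(rbind, placed)
    truth$tissues <- tissues
    truth$planted_fold <- config$enrichment_fold
    truth$has_motif <- runif(n_peaks) < config$motif_plant_rate
    k <- nchar(config$motif)
    for (i in which(truth$has_motif)) {
      centre <- (truth$start[i] + truth$end[i]) %/% 2L
      at <- centre - k %/% 2L  # 0-based; motif spans centre +/- 2 nt for k=5
      tx <- truth$transcript_id[i]
      substr(seqs[[tx]], at + 1L, at + k) <- config$motif
    }
    list(truth = truth, sequences = seqs)
  })
}

# non-overlapping 100-nt generation windows tiling a transcript (last
# window absorbs the remainder)
sim_windows <- function(len, width = 100L) {
  if (len <= width) return(data.frame(start = 0L, end = len))
  starts <- seq(0L, len - width, by = width)
  ends <- starts + width
  ends[length(ends)] <- len
  data.frame(start = starts, end = ends)
}

#' Simulate IP and input aligned reads for every sample
#'
#' For each tissue (A, B), replicate (1, 2) and assay (IP, input), window
#' counts are drawn per non-overlapping 100-nt transcript window from a
#' negative binomial with mean `base_depth` (size = `dispersion`); IP
#' windows overlapping a truth peak active in that tissue have their mean
#' multiplied by `enrichment_fold`. Each read is an interval of length
#' `read_len` whose midpoint is uniform in its window (clipped at
#' transcript ends). Replicates are drawn independently.
#'
#' @param config a [sim_config()].
#' @param annotation result of [sim_annotation()].
#' @param truth data.frame of truth peaks from [sim_plant_truth()].
#' @return nested list `reads[[tissue]][[replicate]][[assay]]`, each a
#'   data.frame with columns `transcript_id`, `start`, `end` (0-based
#'   half-open, transcript space).
#' @export
sim_reads <- function(config, annotation, truth) {
  stopifnot(inherits(config, "sim_config"))
  ann <- annotation$annotation
  half <- config$read_len %/% 2L
  windows <- do.call(rbind, lapply(seq_len(nrow(ann)), function(i) {
    w <- sim_windows(ann$length[i])
    w$transcript_id <- ann$transcript_id[i]
    w$tx_len <- ann$length[i]
    w
  }))
  in_truth <- function(tissue) {
    act <- truth[grepl(tissue, truth$tissues), , drop = FALSE]
    if (is.null(act) || nrow(act) == 0L) return(rep(FALSE, nrow(windows)))
    hit <- rep(FALSE, nrow(windows))
    for (tx in unique(act$transcript_id)) {
      wi <- which(windows$transcript_id == tx)
      ti <- which(act$transcript_id == tx)
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(windows$start[wi] + 1L, windows$end[wi]),
        IRanges::IRanges(act$start[ti] + 1L, act$end[ti]))
      hit[wi[unique(S4Vectors::queryHits(ov))]] <- TRUE
    }
    hit
  }
  enriched <- list(A = in_truth("A"), B = in_truth("B"))
  out <- list()
  offset <- 300L
  for (tissue in c("A", "B")) {
    out[[tissue]] <- list()
    for (rep_i in 1:2) {
      smp <- list()
      for (assay in c("IP", "input")) {
        offset <- offset + 1L
        smp[[assay]] <- with_sim_seed(config, offset, {
          mu <- rep(config$base_depth, nrow(windows)) *
            (windows$end - windows$start) / 100
          if (assay == "IP")
            mu[enriched[[tissue]]] <- mu[enriched[[tissue]]] * config$enrichment_fold
          counts <- rnbinom(length(mu), size = config$dispersion, mu = mu)
          idx <- rep.int(seq_along(counts), counts)
          mid <- windows$start[idx] +
            floor(runif(length(idx)) * (windows$end[idx] - windows$start[idx]))
          start <- pmax(0L, as.integer(mid) - half)
          end <- pmin(windows$tx_len[idx], as.integer(mid) + (config$read_len - half))
          data.frame(transcript_id = windows$transcript_id[idx],
                     start = start, end = end, stringsAsFactors = FALSE)
        })
      }
      out[[tissue]][[rep_i]] <- smp
    }
  }
  out
}

#' Simulate a FASTQ file exercising the read-QC filters
#'
#' Builds reads whose first `insert_len` bases are the clean insert; with
#' probability `adapter_frac` the adapter sequence (with `adapter_mismatch`
#' random substitutions) is written immediately after the insert and the
#' remainder filled with random bases. Base qualities are high (Q35-40)
#' over the insert; with probability `low_qual_frac` a read gets a
#' low-quality (below Q20) 3'-terminal tail.
#'
#' @param config a [sim_config()] (supplies the seed).
#' @param n_reads number of reads.
#' @param adapter adapter sequence planted (default the Illumina prefix
#'   GATCGGAAGA used by the QC stage).
#' @param adapter_frac fraction of reads carrying the adapter.
#' @param adapter_mismatch number of substitutions applied to each planted
#'   adapter copy (0-2).
#' @param insert_len_range range of clean insert lengths, nt.
#' @param read_len total read length, nt.
#' @param low_qual_frac fraction of reads given a low-quality 3' tail.
#' @return reads data.frame (`id`, `bases`, `quals` Phred+33) with a
#'   logical attribute-free column `has_adapter` recording the truth.
#' @export
sim_fastq <- function(config, n_reads = 1000L, adapter = "GATCGGAAGA",
                      adapter_frac = 0.5, adapter_mismatch = 0L,
                      insert_len_range = c(40L, 90L), read_len = 110L,
                      low_qual_frac = 0.2) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config, 909L, {
    ins_len <- sample(seq(insert_len_range[1], insert_len_range[2]),
                      n_reads, replace = TRUE)
    has_adapter <- runif(n_reads) < adapter_frac
    bases <- character(n_reads)
    for (i in seq_len(n_reads)) {
      s <- random_dna(read_len)
      ins <- substr(s, 1L, ins_len[i])
      if (has_adapter[i]) {
        ad <- adapter
        if (adapter_mismatch > 0L) {
          pos <- sample.int(nchar(adapter), adapter_mismatch)
          for (p in pos) {
            cur <- substr(ad, p, p)
            substr(ad, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
          }
        }
        tail_len <- read_len - ins_len[i] - nchar(ad)
        bases[i] <- paste0(ins, ad,
                           if (tail_len > 0) random_dna(tail_len) else "")
        bases[i] <- substr(bases[i], 1L, read_len)
      } else {
        bases[i] <- s
      }
    }
    quals <- character(n_reads)
    low_tail <- runif(n_reads) < low_qual_frac
    for (i in seq_len(n_reads)) {
      L <- nchar(bases[i])
      q <- sample(35:40, L, replace = TRUE)
      if (low_tail[i]) {
        tl <- sample(5:15, 1L)
        q[(L - tl + 1L):L] <- sample(2:19, tl, replace = TRUE)
      }
      quals[i] <- phred_to_string(q)
    }
    data.frame(id = sprintf("read%06d", seq_len(n_reads)),
               bases = bases, quals = quals, has_adapter = has_adapter,
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic two-tissue MeRIP-seq dataset
#'
#' Convenience wrapper chaining [sim_annotation()], [sim_plant_truth()] and
#' [sim_reads()].
#'
#' @param config a [sim_config()].
#' @return list with `annotation`, `sequences` (motif-planted), `truth`
#'   and `reads`.
#' @export
sim_dataset <- function(config = sim_config()) {
  ann <- sim_annotation(config)
  pt <- sim_plant_truth(config, ann)
  ann$sequences <- pt$sequences
  reads <- sim_reads(config, ann, pt$truth)
  list(annotation = ann$annotation, sequences = pt$sequences,
       truth = pt$truth, reads = reads)
}

#' Write a synthetic dataset to disk in standard formats
#'
#' GTF annotation (1-based closed), FASTA transcript sequences, BED6 truth
#' peaks (name = tissues, score = planted fold) and one BED6 file of read
#' intervals per (tissue, replicate, assay).
#'
#' @param dataset result of [sim_dataset()].
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(gtf = file.path(dir, "annotation.gtf"),
             fasta = file.path(dir, "transcripts.fa"),
             truth = file.path(dir, "truth_peaks.bed"))
  write_gtf(dataset$annotation, paths["gtf"])
  write_fasta(dataset$sequences, paths["fasta"])
  truth <- dataset$truth
  truth$name <- truth$tissues
  truth$score <- truth$planted_fold
  write_bed(truth, paths["truth"])
  for (tissue in names(dataset$reads))
    for (rep_i in seq_along(dataset$reads[[tissue]]))
      for (assay in names(dataset$reads[[tissue]][[rep_i]])) {
        key <- sprintf("%s_rep%d_%s", tissue, rep_i, assay)
        p <- file.path(dir, paste0("reads_", key, ".bed"))
        write_bed(dataset$reads[[tissue]][[rep_i]][[assay]], p)
        paths[key] <- p
      }
  invisible(paths)
}
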