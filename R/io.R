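#' @include AllClasses.R constructors.R
NULL

#' Read biallelic SNP genotypes from VCF
#'
#' Supports the minimal VCF v4.2 dialect (biallelic SNP records, diploid GT
#' subfield); multi-allelic or non-SNP records are skipped and counted.
#' File positions are 1-based; internally positions are stored 0-based.
#'
#' @param path VCF file path.
#' @param metadata data.frame with columns `sample`, `population`, `ecotype`,
#'   `habitat`, one row per sample in the file.
#' @return a [GenotypeTable-class]; skipped-record counts are attached as
#'   attribute `"skipped"` of the object's metadata.
#' @export
readGenotypeVcf <- function(path, metadata) {
  if (!all(c("sample", "population", "ecotype", "habitat") %in%
           names(metadata)))
    stop("metadata needs columns sample, population, ecotype, habitat")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- rbind(fix)
  snp <- fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  nSkipped <- sum(!snp)
  if (nSkipped) message(nSkipped, " non-biallelic-SNP record(s) skipped")
  gtRaw <- vcfR::extract.gt(v, element = "GT")
  gtRaw <- rbind(gtRaw)[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]

  parse1 <- function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(x, "[/|]")[[1]]
    if (length(al) != 2L) stop("non-diploid GT field: ", x)
    if (any(al == ".")) return(NA_integer_)
    sum(al == "1")
  }
  g <- apply(gtRaw, c(1, 2), parse1)
  ix <- match(colnames(g), metadata$sample)
  if (anyNA(ix)) stop("samples missing from metadata: ",
                      paste(colnames(g)[is.na(ix)], collapse = ", "))
  md <- metadata[ix, c("population", "ecotype", "habitat"), drop = FALSE]
  rownames(md) <- metadata$sample[ix]
  siteInfo <- data.frame(
    locus = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]) - 1L,
    ref = fix[, "REF"], alt = fix[, "ALT"], stringsAsFactors = FALSE)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste(siteInfo$locus, siteInfo$pos,
                                        sep = "_")[is.na(ids) | ids == "."]
  rownames(g) <- ids
  out <- GenotypeTable(g, siteInfo, md)
  S4Vectors::metadata(out)$skipped <- nSkipped
  out
}

#' Write genotypes as minimal VCF v4.2
#'
#' Biallelic SNP records with a GT-only FORMAT; internal 0-based positions are
#' written 1-based.
#'
#' @param gt a [GenotypeTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(gt, path) {
  g <- SummarizedExperiment::assay(gt, "GT")
  rd <- SummarizedExperiment::rowData(gt)
  code <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(g)), function(i) {
    gts <- ifelse(is.na(g[i, ]), "./.", code[g[i, ] + 1L])
    paste(c(rd$locus[i], rd$pos[i] + 1L, rownames(g)[i], rd$ref[i],
            rd$alt[i], ".", ".", ".", "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=radpop",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(g)), collapse = "\t"),
               body), path)
  invisible(path)
}

#' Sample metadata of a genotype table as a data.frame
#' @param gt a [GenotypeTable-class].
#' @return data.frame with `sample`, `population`, `ecotype`, `habitat`.
#' @export
sampleMetadata <- function(gt) {
  cd <- SummarizedExperiment::colData(gt)
  data.frame(sample = rownames(cd), population = cd$population,
             ecotype = cd$ecotype, habitat = cd$habitat,
             stringsAsFactors = FALSE)
}

#' Read / write per-locus haplotype alignments as FASTA
#'
#' Header grammar: `>sampleid|pop|ecotype|locus` with an optional fifth field
#' `outgroup` routing the record to the locus's outgroup slot. Sequences are
#' full-length 0/1 strings (one character per bp; monomorphic positions are
#' `0`); on reading, the polymorphic columns become the locus's segregating
#' sites. Ragged alignments within a locus and duplicate sample-locus pairs
#' are errors.
#'
#' @param path FASTA file path.
#' @return `readHaplotypesFasta` returns a [HaplotypeSet-class];
#'   `writeHaplotypesFasta` returns `path` invisibly.
#' @export
readHaplotypesFasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4L | nf > 5L))
    stop("malformed FASTA header(s): expected sampleid|pop|ecotype|locus[|outgroup]")
  info <- data.frame(
    sample = vapply(parts, `[`, "", 1L),
    pop = vapply(parts, `[`, "", 2L),
    ecotype = vapply(parts, `[`, "", 3L),
    locus = vapply(parts, `[`, "", 4L),
    outgroup = vapply(parts, function(p) length(p) == 5L && p[5] == "outgroup",
                      logical(1)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(info[c("sample", "locus")]))
    stop("duplicate sample-locus pairs in FASTA")
  lens <- Biostrings::width(seqs)
  loci <- list()
  lens0 <- integer(0)
  for (nm in unique(info$locus)) {
    sel <- info$locus == nm
    if (length(unique(lens[sel])) != 1L)
      stop("ragged alignment at locus ", nm)
    lens0 <- c(lens0, lens[sel][1])
    chars <- do.call(rbind, strsplit(as.character(seqs[sel]), ""))
    if (!all(chars %in% c("0", "1")))
      stop("locus ", nm, ": alleles must be 0/1")
    m <- matrix(as.integer(chars), nrow = sum(sel))
    isOut <- info$outgroup[sel]
    og <- if (any(isOut)) m[which(isOut)[1], ] else NULL
    mi <- m[!isOut, , drop = FALSE]
    segg <- colSums(rbind(mi, og)) > 0
    loci[[nm]] <- list(h = mi[, segg, drop = FALSE],
                       positions = which(segg) - 1L,
                       group = info$pop[sel][!isOut],
                       ecotype = info$ecotype[sel][!isOut],
                       samples = info$sample[sel][!isOut],
                       class = NA_character_,
                       outgroup = if (is.null(og)) NULL else og[segg])
  }
  if (length(unique(lens0)) != 1L)
    stop("loci have differing alignment lengths")
  HaplotypeSet(loci, lens0[1])
}

#' @rdname readHaplotypesFasta
#' @param hs a [HaplotypeSet-class].
#' @param ecotypes optional named map from group label to ecotype written in
#'   the header (defaults to the per-locus `ecotype` field or `"NA"`).
#' @export
writeHaplotypesFasta <- function(hs, path, ecotypes = NULL) {
  recs <- character(0)
  for (nm in names(hs@loci)) {
    loc <- hs@loci[[nm]]
    full <- matrix("0", nrow(loc$h), hs@locusLength)
    if (ncol(loc$h))
      full[, loc$positions + 1L] <- as.character(loc$h)
    samples <- loc$samples %||% sprintf("hap%03d", seq_len(nrow(loc$h)))
    ecs <- if (!is.null(ecotypes)) unname(ecotypes[loc$group])
           else loc$ecotype %||% rep("NA", nrow(loc$h))
    hdr <- sprintf(">%s|%s|%s|%s", samples, loc$group, ecs, nm)
    recs <- c(recs, rbind(hdr, apply(full, 1, paste, collapse = "")))
    if (!is.null(loc$outgroup)) {
      ofull <- rep("0", hs@locusLength)
      if (ncol(loc$h)) ofull[loc$positions + 1L] <- as.character(loc$outgroup)
      recs <- c(recs, sprintf(">outg|outg|NA|%s|outgroup", nm),
                paste(ofull, collapse = ""))
    }
  }
  writeLines(recs, path)
  invisible(path)
}
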