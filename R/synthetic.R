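#' Generate a random motif
#'
#' Each column gives the consensus base frequency \code{conservation} and
#' splits the remainder uniformly over the other three bases; the consensus
#' sequence itself is drawn uniformly from the seeded RNG.
#'
#' @param motif_id Identifier.
#' @param width Motif width (>= 4).
#' @param conservation Consensus base frequency per column, in (0, 1].
#' @param seed RNG seed.
#' @return A \code{crm_motif}.
#' @export
random_motif <- function(motif_id, width = 8L, conservation = 1.0, seed = 1L) {
  stopifnot(width >= 4, conservation > 0, conservation <= 1)
  cons <- with_seed(seed, sample.int(4L, width, replace = TRUE))
  pfm <- matrix((1 - conservation) / 3, 4, width)
  pfm[cbind(cons, seq_len(width))] <- conservation
  motif(motif_id, pfm)
}

#' Define one element of a planted structural grammar
#'
#' Three placement kinds are supported: \code{tss_distance} plants the motif
#' in a 100-bp distance bin from the TSS (\code{dir} "u" upstream or "d"
#' downstream) on a fixed or random ("either") strand; \code{relative_to}
#' plants a pair of motifs whose start-to-start spacing falls in a 100-bp
#' bin, with a strand constraint per motif; \code{order} plants 2-3 motifs at
#' random non-overlapping positions in the given 5'-to-3' order.
#'
#' @param motif_id Motif id (first motif for pair/order elements).
#' @param kind "tss_distance", "relative_to" or "order".
#' @param bin 100-bp bin index (tss_distance, relative_to).
#' @param dir "u" or "d" (tss_distance only).
#' @param strand "+", "-" or "either" (tss_distance), or length-2 vector for
#'   relative_to.
#' @param partner Second motif id (relative_to).
#' @param order_motifs Character vector of 2-3 motif ids (order).
#' @param p_pos,p_neg Plant probability in positive / negative regions.
#' @return List of class \code{crm_grammar_element}.
#' @export
grammar_element <- function(motif_id, kind = c("tss_distance", "relative_to",
                                               "order"),
                            bin = 0L, dir = "u", strand = "either",
                            partner = NULL, order_motifs = NULL,
                            p_pos = 0.9, p_neg = 0.05) {
  kind <- match.arg(kind)
  stopifnot(p_pos >= 0, p_pos <= 1, p_neg >= 0, p_neg <= 1, bin >= 0)
  if (kind == "relative_to" && is.null(partner))
    stop("relative_to element needs a partner motif")
  if (kind == "order") {
    if (is.null(order_motifs)) order_motifs <- motif_id
    if (length(order_motifs) < 2 || length(order_motifs) > 3)
      stop("order element needs 2-3 motifs")
  }
  if (kind == "tss_distance" && !dir %in% c("u", "d"))
    stop("dir must be 'u' or 'd'")
  structure(list(motif_id = motif_id, kind = kind, bin = as.integer(bin),
                 dir = dir, strand = strand, partner = partner,
                 order_motifs = order_motifs, p_pos = p_pos, p_neg = p_neg),
            class = "crm_grammar_element")
}

#' Default planted grammar of the synthetic study
#'
#' Three elements emulating published feature archetypes: one motif in a
#' fixed upstream TSS-distance bin on the plus strand, one in a farther
#' upstream bin on the minus strand, and a same-motif pair spaced within
#' 0-100 bp on the plus strand. Plant probabilities default to 0.9 in
#' positive and 0.05 in negative regions.
#'
#' @param p_pos,p_neg Plant probabilities shared by all elements.
#' @return List of [grammar_element()]s.
#' @export
default_grammar <- function(p_pos = 0.9, p_neg = 0.05) {
  list(
    grammar_element("M1", "tss_distance", bin = 1L, dir = "u", strand = "+",
                    p_pos = p_pos, p_neg = p_neg),
    grammar_element("M2", "tss_distance", bin = 4L, dir = "u", strand = "-",
                    p_pos = p_pos, p_neg = p_neg),
    grammar_element("M3", "relative_to", partner = "M3", bin = 0L,
                    strand = c("+", "+"), p_pos = p_pos, p_neg = p_neg))
}

# Feature ids an element should produce, in acceptability order: the
# strand-specific id first (when the strand is fixed), then the either-strand
# generalisation. Order elements have a single orientation-free id.
#' @noRd
element_truth_features <- function(el, window = 100L) {
  if (el$kind == "tss_distance") {
    base <- paste0("tss|", el$motif_id, "|", el$dir, el$bin, "|")
    if (identical(el$strand, "either")) paste0(base, ".")
    else c(paste0(base, el$strand), paste0(base, "."))
  } else if (el$kind == "relative_to") {
    ms <- c(el$motif_id, el$partner)
    ss <- if (identical(el$strand, "either") || length(el$strand) != 2)
      NULL else el$strand
    o <- order(ms, if (is.null(ss)) c("", "") else ss)
    pair <- paste0("pair|", ms[o[1]], ",", ms[o[2]], "|", el$bin, "|")
    if (is.null(ss)) paste0(pair, "..")
    else c(paste0(pair, ss[o[1]], ss[o[2]]), paste0(pair, ".."))
  } else {
    paste0("order|", paste(el$order_motifs, collapse = ">"))
  }
}

#' @noRd
pick_strand <- function(s) if (identical(s, "either")) sample(c("+", "-"), 1) else s

# Sample an instance sequence of a motif: its consensus, or a draw from the
# PFM columns when mode = "sample".
#' @noRd
motif_instance <- function(m, mode) {
  if (mode == "consensus") consensus(m)
  else decode_seq(vapply(seq_len(m$width), function(j)
    sample.int(4L, 1L, prob = m$pfm[, j]), integer(1)))
}

#' Generate a seeded synthetic study
#'
#' Builds a synthetic genome of TSS-anchored regulatory regions with i.i.d.
#' background sequence, plants each grammar element independently with its
#' class-specific probability at a uniformly drawn admissible location
#' (instances never overlap each other), assigns each gene a random genomic
#' strand, and records the exact ground truth. The genome round-trips
#' through [read_genome()]/[extract_regions()].
#'
#' @param n_pos,n_neg Number of positive / negative regions.
#' @param upstream,downstream Region extent around the TSS (bp).
#' @param grammar List of [grammar_element()]s (default [default_grammar()]).
#' @param motifs Optional named list of \code{crm_motif}; by default an
#'   8-bp fully conserved [random_motif()] is drawn per motif id used by the
#'   grammar.
#' @param base_composition Background base probabilities (A, C, G, T).
#' @param plant_mode "consensus" (deterministic instances, default) or
#'   "sample" (instances drawn from the PFM).
#' @param seed Master seed; the study is a pure function of its arguments.
#' @return Object of class \code{crm_study}: list(genome, tss, motifs,
#'   positives, negatives, truth, truth_features, regions, params).
#' @export
generate_study <- function(n_pos = 100L, n_neg = 500L, upstream = 1500L,
                           downstream = 500L, grammar = default_grammar(),
                           motifs = NULL,
                           base_composition = rep(0.25, 4),
                           plant_mode = c("consensus", "sample"),
                           seed = 1L) {
  plant_mode <- match.arg(plant_mode)
  stopifnot(n_pos >= 1, n_neg >= 1)
  len <- as.integer(upstream + downstream)
  need_ids <- unique(unlist(lapply(grammar, function(el)
    c(el$motif_id, el$partner, el$order_motifs))))
  if (is.null(motifs)) {
    motifs <- lapply(seq_along(need_ids), function(k)
      random_motif(need_ids[k], width = 8L, conservation = 1.0,
                   seed = sub_seed(seed, 31L, k)))
    names(motifs) <- need_ids
  }
  if (!all(need_ids %in% names(motifs)))
    stop("grammar references motifs not provided: ",
         paste(setdiff(need_ids, names(motifs)), collapse = ", "))
  widths <- vapply(motifs, `[[`, numeric(1), "width")
  window <- 100L
  # satisfiability before generation
  for (el in grammar) {
    w <- widths[[el$motif_id]]
    if (el$kind == "tss_distance") {
      lims <- if (el$dir == "u") upstream else downstream - w + 1L
      if (window * el$bin >= lims)
        stop("element '", el$motif_id, "' bin ", el$bin,
             " does not fit in the region")
    } else if (el$kind == "relative_to") {
      if (window * el$bin + widths[[el$partner]] + w > len)
        stop("pair element '", el$motif_id, "' bin ", el$bin,
             " does not fit in the region")
    } else {
      if (sum(widths[el$order_motifs]) > len)
        stop("order element does not fit in the region")
    }
  }
  p <- base_composition / sum(base_composition)
  gen_region <- function(is_pos, rseed) {
    with_seed(rseed, {
      chars <- sample(DNA_BASES, len, replace = TRUE, prob = p)
      occupied <- matrix(numeric(0), ncol = 2)   # [start, end) 0-based
      free <- function(s, w) !any(s < occupied[, 2] & s + w > occupied[, 1])
      put <- function(s, m, strand) {
        inst <- motif_instance(motifs[[m]], plant_mode)
        if (strand == "-") inst <- revcomp_chr(inst)
        chars[(s + 1):(s + nchar(inst))] <<- strsplit(inst, "")[[1]]
        occupied <<- rbind(occupied, c(s, s + nchar(inst)))
      }
      truth <- list()
      for (ei in seq_along(grammar)) {
        el <- grammar[[ei]]
        if (stats::runif(1) >= (if (is_pos) el$p_pos else el$p_neg)) next
        planted <- FALSE
        for (try in 1:200) {
          if (el$kind == "tss_distance") {
            w <- widths[[el$motif_id]]
            d <- el$bin * window + sample.int(window, 1L) - 1L
            start <- if (el$dir == "u") -d else d        # TSS-relative
            s <- upstream + start                        # 0-based seq pos
            if (s < 0 || s + w > len || !free(s, w)) next
            st <- pick_strand(el$strand)
            put(s, el$motif_id, st)
            truth[[length(truth) + 1]] <- data.frame(
              element = ei, motif_id = el$motif_id, start = start,
              strand = st)
          } else if (el$kind == "relative_to") {
            w1 <- widths[[el$motif_id]]; w2 <- widths[[el$partner]]
            dlo <- max(el$bin * window, w1)
            dhi <- (el$bin + 1L) * window - 1L
            if (dlo > dhi) stop("pair bin ", el$bin, " narrower than motif")
            d <- dlo + sample.int(dhi - dlo + 1L, 1L) - 1L
            s1 <- sample.int(len - d - w2 + 1L, 1L) - 1L
            s2 <- s1 + d
            if (!free(s1, w1) || !free(s2, w2)) next
            ss <- if (identical(el$strand, "either"))
              c(pick_strand("either"), pick_strand("either")) else el$strand
            put(s1, el$motif_id, ss[1]); put(s2, el$partner, ss[2])
            truth[[length(truth) + 1]] <- data.frame(
              element = ei, motif_id = c(el$motif_id, el$partner),
              start = c(s1, s2) - upstream, strand = ss)
          } else {
            k <- length(el$order_motifs)
            ws <- widths[el$order_motifs]
            ss <- sort(sample.int(len - max(ws) + 1L, k) - 1L)
            ok <- all(diff(ss) >= ws[-k]) &&
              all(vapply(seq_len(k), function(q) free(ss[q], ws[q]),
                         logical(1)))
            if (!ok) next
            sts <- vapply(seq_len(k), function(q) pick_strand("either"),
                          character(1))
            for (q in seq_len(k)) put(ss[q], el$order_motifs[q], sts[q])
            truth[[length(truth) + 1]] <- data.frame(
              element = ei, motif_id = el$order_motifs,
              start = ss - upstream, strand = sts)
          }
          planted <- TRUE
          break
        }
        if (!planted)
          warning("could not place element ", ei, " after 200 attempts")
      }
      list(seq = paste(chars, collapse = ""),
           truth = if (length(truth)) do.call(rbind, truth) else NULL)
    })
  }
  n <- n_pos + n_neg
  ids <- c(sprintf("pos_%04d", seq_len(n_pos)),
           sprintf("neg_%04d", seq_len(n_neg)))
  seqs <- character(n)
  truth <- list()
  for (i in seq_len(n)) {
    g <- gen_region(i <= n_pos, sub_seed(seed, 53L, i))
    seqs[i] <- g$seq
    if (!is.null(g$truth))
      truth[[length(truth) + 1]] <- cbind(gene_id = ids[i], g$truth)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(0), element = integer(0),
               motif_id = character(0), start = integer(0),
               strand = character(0))
  # assemble a single chromosome; each gene gets a random genomic strand
  gstrand <- with_seed(sub_seed(seed, 97L), sample(c("+", "-"), n, TRUE))
  blocks <- ifelse(gstrand == "+", seqs, revcomp_chr(seqs))
  starts0 <- cumsum(c(0L, rep(len, n - 1L)))          # 0-based block starts
  tss <- data.frame(gene_id = ids, chrom = "chrS", strand = gstrand,
                    tss = as.integer(ifelse(gstrand == "+",
                                            starts0 + upstream,
                                            starts0 + downstream - 1L)),
                    stringsAsFactors = FALSE)
  genome <- c(chrS = paste(blocks, collapse = ""))
  structure(list(genome = genome, tss = tss, motifs = motifs,
                 positives = ids[seq_len(n_pos)],
                 negatives = ids[n_pos + seq_len(n_neg)],
                 truth = truth,
                 truth_features = lapply(grammar, element_truth_features),
                 regions = regions(ids, seqs, upstream, downstream),
                 params = list(n_pos = n_pos, n_neg = n_neg,
                               upstream = as.integer(upstream),
                               downstream = as.integer(downstream),
                               base_composition = p,
                               plant_mode = plant_mode, seed = seed)),
            class = "crm_study")
}

#' @export
print.crm_study <- function(x, ...) {
  cat(sprintf("<crm_study> %d positive + %d negative regions of %d bp, %d motifs, %d planted instances (seed %d)\n",
              x$params$n_pos, x$params$n_neg,
              x$params$upstream + x$params$downstream, length(x$motifs),
              nrow(x$truth), x$params$seed))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits exactly the formats the reading functions consume: genome.fa,
#' tss.tsv, motifs.jaspar, positives.txt, negatives.txt and truth.json.
#'
#' @param study A \code{crm_study}.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(out_dir, "genome.fa"),
             tss = file.path(out_dir, "tss.tsv"),
             motifs = file.path(out_dir, "motifs.jaspar"),
             positives = file.path(out_dir, "positives.txt"),
             negatives = file.path(out_dir, "negatives.txt"),
             truth = file.path(out_dir, "truth.json"))
  dna <- Biostrings::DNAStringSet(study$genome)
  Biostrings::writeXStringSet(dna, paths["genome"], width = 80L)
  utils::write.table(study$tss, paths["tss"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_motifs_jaspar(study$motifs, paths["motifs"])
  writeLines(study$positives, paths["positives"])
  writeLines(study$negatives, paths["negatives"])
  jsonlite::write_json(
    list(truth = study$truth,
         truth_features = study$truth_features,
         params = study$params),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
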