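#' Construct a germline gene record
#'
#' @param name gene identifier.
#' @param segment `"V"` or `"J"`.
#' @param sequence nucleotide string over ACGT.
#' @param regions optional region map on the gene's own coordinates
#'   (V genes only): data frame `region`/`start`/`end`, 0-based half-open.
#' @return a `germline_gene` list.
#' @export
germline_gene <- function(name, segment, sequence, regions = NULL) {
  segment <- match.arg(segment, c("V", "J"))
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("germline sequence must be non-empty")
  if (grepl("[^ACGT]", sequence)) {
    stop("germline gene ", name, " contains non-ACGT bases")
  }
  if (!is.null(regions)) {
    regions <- region_map(regions$region, regions$start, regions$end)
    if (any(regions$end > nchar(sequence))) {
      stop("region interval outside gene ", name)
    }
  }
  structure(list(name = name, segment = segment, sequence = sequence,
                 regions = regions), class = "germline_gene")
}

#' Read a germline V/J library from FASTA plus a region config
#'
#' @param v_fasta,j_fasta FASTA files of germline V and J genes.
#' @param regions_json optional JSON file (or pre-parsed list) mapping V
#'   gene names to region intervals:
#'   `{"V1": {"CDR2": [start, end], "FWR3": [...], "CDR3": [...]}, ...}`,
#'   0-based half-open on the gene.
#' @return list of `germline_gene` objects, V genes first, in file order.
#' @export
read_germline_library <- function(v_fasta, j_fasta, regions_json = NULL) {
  regions <- NULL
  if (!is.null(regions_json)) {
    regions <- if (is.character(regions_json)) {
      jsonlite::read_json(regions_json, simplifyVector = TRUE)
    } else regions_json
  }
  vs <- read_fasta(v_fasta)
  js <- read_fasta(j_fasta)
  lib <- c(
    lapply(seq_along(vs), function(i) {
      nm <- names(vs)[i]
      reg <- NULL
      if (!is.null(regions) && nm %in% names(regions)) {
        rr <- regions[[nm]]
        reg <- data.frame(region = names(rr),
                          start = vapply(rr, function(x) x[1], numeric(1)),
                          end = vapply(rr, function(x) x[2], numeric(1)))
      }
      germline_gene(nm, "V", vs[[i]], reg)
    }),
    lapply(seq_along(js), function(i) germline_gene(names(js)[i], "J", js[[i]]))
  )
  lib
}

# best ungapped placement of one gene against an encoded read.
# offsets are 0-based positions of the gene start on the read and may run
# off the read's 5' end (V) or 3' end (J); the scored overlap must contain
# at least min(gene length, min_overlap) read positions, and the anchor end
# of the gene (3' for V, 5' for J) must lie on the read. Read positions
# with non-ACGT symbols are excluded from both numerator and denominator.
best_placement <- function(read_int, gene_int, min_overlap,
                           offset_range) {
  Lr <- length(read_int); Lg <- length(gene_int)
  best <- list(fraction = -Inf, offset = NA_integer_)
  for (o in offset_range) {
    a <- max(0L, o); b <- min(Lr, o + Lg) - 1L      # read window, 0-based
    if (b - a + 1L < min(Lg, min_overlap)) next
    rseg <- read_int[(a + 1L):(b + 1L)]
    gseg <- gene_int[(a - o + 1L):(b - o + 1L)]
    valid <- !is.na(rseg)
    denom <- sum(valid)
    if (denom == 0L) next
    frac <- sum(rseg[valid] == gseg[valid]) / denom
    if (frac > best$fraction) best <- list(fraction = frac, offset = o)
  }
  best
}

#' Assign the best-matching germline V and J genes to a read
#'
#' Every germline gene is slid without gaps along the read (somatic
#' hypermutation is assumed indel-free) and scored by the fraction of
#' matching positions over the aligned overlap; the V gene and placement
#' maximising this fraction are chosen first, then the J gene constrained
#' to start after the V end. Ties keep the first-seen candidate (library
#' file order, then smaller offset).
#'
#' @param sequence the read (nucleotide string, length >= 60).
#' @param library list of `germline_gene`s with at least one V and one J.
#' @param sequence_id id recorded in the result.
#' @param min_overlap_v,min_overlap_j minimum aligned overlap for a
#'   placement to be scored.
#' @return one-row data frame: `sequence_id`, `v_gene`, `j_gene`,
#'   `v_match_fraction`, `j_match_fraction`, `v_start_pos`, `v_end_pos`,
#'   `j_start_pos`, `vj_distance` (all positions 0-based on the read).
#'   All-`NA` fields (except the id) signal an assignment failure
#'   (no feasible placement).
#' @export
assign_germline <- function(sequence, library, sequence_id = "seq",
                            min_overlap_v = 60L, min_overlap_j = 15L) {
  vg <- Filter(function(g) g$segment == "V", library)
  jg <- Filter(function(g) g$segment == "J", library)
  if (!length(vg) || !length(jg)) {
    stop("library must contain at least one V and one J gene")
  }
  if (nchar(sequence) < 60L) stop("read shorter than 60 nt")
  read_int <- seq_to_int(stats::setNames(sequence, "r"))[1, ]
  Lr <- length(read_int)

  failure <- data.frame(sequence_id = sequence_id, v_gene = NA_character_,
                        j_gene = NA_character_, v_match_fraction = NA_real_,
                        j_match_fraction = NA_real_, v_start_pos = NA_integer_,
                        v_end_pos = NA_integer_, j_start_pos = NA_integer_,
                        vj_distance = NA_integer_, stringsAsFactors = FALSE)

  best_v <- list(fraction = -Inf)
  for (g in vg) {
    gi <- seq_to_int(stats::setNames(g$sequence, g$name))[1, ]
    Lg <- length(gi)
    # V: 3' end of the gene must lie on the read (it anchors truncation)
    o_min <- -(Lg - min(Lg, min_overlap_v))
    o_max <- Lr - Lg
    if (o_max < o_min) next
    bp <- best_placement(read_int, gi, min_overlap_v, o_min:o_max)
    if (bp$fraction > best_v$fraction) {
      best_v <- c(bp, list(gene = g$name, Lg = Lg))
    }
  }
  if (!is.finite(best_v$fraction)) return(failure)
  v_end <- best_v$offset + best_v$Lg - 1L
  v_start <- max(0L, best_v$offset)

  best_j <- list(fraction = -Inf)
  for (g in jg) {
    gi <- seq_to_int(stats::setNames(g$sequence, g$name))[1, ]
    Lg <- length(gi)
    # J: gene start must lie on the read, after the V end
    o_min <- v_end + 1L
    o_max <- Lr - min(Lg, min_overlap_j)
    if (o_max < o_min) next
    bp <- best_placement(read_int, gi, min_overlap_j, o_min:o_max)
    if (bp$fraction > best_j$fraction) {
      best_j <- c(bp, list(gene = g$name))
    }
  }
  if (!is.finite(best_j$fraction)) return(failure)

  data.frame(sequence_id = sequence_id, v_gene = best_v$gene,
             j_gene = best_j$gene, v_match_fraction = best_v$fraction,
             j_match_fraction = best_j$fraction, v_start_pos = v_start,
             v_end_pos = v_end, j_start_pos = best_j$offset,
             vj_distance = best_j$offset - v_end - 1L,
             stringsAsFactors = FALSE)
}

#' Assign germlines to a whole read set
#'
#' @param reads named character vector of reads.
#' @param library germline library.
#' @param ... passed to [assign_germline()].
#' @return data frame with one row per read (failed assignments carry NA).
#' @export
assign_germline_all <- function(reads, library, ...) {
  if (length(reads) == 0L) {
    return(data.frame(sequence_id = character(), v_gene = character(),
                      j_gene = character(), v_match_fraction = numeric(),
                      j_match_fraction = numeric(), v_start_pos = integer(),
                      v_end_pos = integer(), j_start_pos = integer(),
                      vj_distance = integer(), stringsAsFactors = FALSE))
  }
  out <- lapply(seq_along(reads), function(i) {
    assign_germline(reads[[i]], library, sequence_id = names(reads)[i], ...)
  })
  do.call(rbind, out)
}

#' Keep assignments matching both segments above a threshold
#'
#' @param assignments data frame from [assign_germline_all()].
#' @param threshold minimum match fraction, strict (`> threshold`) in both
#'   V and J.
#' @return the retained rows.
#' @export
filter_assignments <- function(assignments, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0,1]")
  keep <- !is.na(assignments$v_match_fraction) &
    !is.na(assignments$j_match_fraction) &
    assignments$v_match_fraction > threshold &
    assignments$j_match_fraction > threshold
  assignments[keep, , drop = FALSE]
}

#' Group assigned reads by (V, J, V-J distance) and truncate them
#'
#' Reads sharing the same inferred V gene, J gene and V-J junction length
#' necessarily derive from rearrangements with the same junction geometry
#' (hypermutation is indel-free), so they are candidate members of the same
#' clone. Each member is truncated to the analysis window: the last
#' `v_trunc` nt of the aligned V, the junction, and the first `j_trunc` nt
#' of the aligned J — a contiguous read slice of length
#' `v_trunc + vj_distance + j_trunc`. Each group also receives an
#' artificial germline reference (truncated germline V + `N`-filled
#' junction + truncated germline J); the `N`s mark the junction as
#' unknowable from the germline and are excluded from mutation counting.
#'
#' @param assignments filtered assignment data frame.
#' @param reads named character vector of the reads.
#' @param library germline library (for the reference sequences).
#' @param v_trunc,j_trunc truncation anchors in nt; the default 159/20
#'   keeps the frame (159 = 53 codons).
#' @return list of `clone_group`s: each has `v_gene`, `j_gene`,
#'   `vj_distance`, `members` (named truncated sequences), `germline`,
#'   `region_map` (if the V gene carries region annotations). The
#'   `dropped` attribute lists reads too short to truncate.
#' @export
group_and_truncate <- function(assignments, reads, library,
                               v_trunc = 159L, j_trunc = 20L) {
  genes <- stats::setNames(library, vapply(library, `[[`, "", "name"))
  dropped <- character(0)
  kept <- list()
  for (i in seq_len(nrow(assignments))) {
    a <- assignments[i, ]
    read <- reads[[a$sequence_id]]
    start0 <- a$v_end_pos - v_trunc + 1L          # 0-based window start
    end0 <- a$j_start_pos + j_trunc               # 0-based, exclusive
    v_covered <- a$v_end_pos - a$v_start_pos + 1L >= v_trunc
    if (!v_covered || start0 < 0L || end0 > nchar(read)) {
      dropped <- c(dropped, a$sequence_id)
      next
    }
    key <- paste(a$v_gene, a$j_gene, a$vj_distance, sep = "|")
    kept[[key]] <- rbind(kept[[key]], data.frame(
      id = a$sequence_id,
      seq = substr(read, start0 + 1L, end0),
      v_gene = a$v_gene, j_gene = a$j_gene, vj_distance = a$vj_distance,
      stringsAsFactors = FALSE))
  }
  if (length(dropped)) {
    warning(length(dropped), " read(s) too short to truncate were dropped")
  }
  groups <- lapply(kept, function(df) {
    vs <- genes[[df$v_gene[1]]]$sequence
    js <- genes[[df$j_gene[1]]]$sequence
    if (nchar(vs) < v_trunc || nchar(js) < j_trunc) {
      stop("germline gene shorter than the truncation window")
    }
    vjd <- df$vj_distance[1]
    germ <- paste0(substr(vs, nchar(vs) - v_trunc + 1L, nchar(vs)),
                   strrep("N", vjd), substr(js, 1L, j_trunc))
    rmaps <- region_map_for_group(genes[[df$v_gene[1]]], vjd,
                                  v_trunc, j_trunc)
    structure(list(v_gene = df$v_gene[1], j_gene = df$j_gene[1],
                   vj_distance = vjd,
                   members = stats::setNames(df$seq, df$id),
                   germline = germ, region_map = rmaps),
              class = "clone_group")
  })
  attr(groups, "dropped") <- dropped
  groups
}

#' Region map of a clone group's truncated frame
#'
#' Maps the V gene's region annotations into truncated-window coordinates
#' and appends/extends a CDR3 interval covering the junction and the J
#' stub (the J region is analysed as part of CDR3, which avoids artifacts
#' of the unknown D-segment length).
#'
#' @param v_gene a `germline_gene` (segment V), possibly annotated.
#' @param vj_distance junction length of the group.
#' @param v_trunc,j_trunc truncation anchors.
#' @return region-map data frame on the truncated frame, or `NULL` when
#'   the V gene carries no annotations.
#' @export
region_map_for_group <- function(v_gene, vj_distance,
                                 v_trunc = 159L, j_trunc = 20L) {
  total <- v_trunc + vj_distance + j_trunc
  shift <- nchar(v_gene$sequence) - v_trunc
  if (is.null(v_gene$regions)) {
    return(region_map("CDR3", v_trunc, total))
  }
  rr <- v_gene$regions
  rr$start <- pmax(rr$start - shift, 0L)
  rr$end <- pmin(rr$end - shift, v_trunc)
  rr <- rr[rr$end > rr$start, , drop = FALSE]
  if ("CDR3" %in% rr$region) {
    rr$end[rr$region == "CDR3"] <- total      # extend through junction + J
  } else {
    rr <- rbind(rr, data.frame(region = "CDR3", start = v_trunc,
                               end = total))
  }
  region_map(rr$region, rr$start, rr$end)
}
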