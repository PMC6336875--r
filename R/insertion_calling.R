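## Junction-read insertion calling: locate the reference/cassette junction in
## a read, convert it to an insertion call (nucleotide position, orientation,
## frame, productive status), reconcile mates, and tally per-residue counts.
##
## Coordinates are 0-based half-open internally; aa_pos is reported 1-based
## ("inserted after residue aa_pos"; 0 = before residue 1). The duplicated
## 5-mer is assigned to the reference and nt_pos is its first base.

.count_occurrences <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (length(hits) == 1 && hits[1] == -1L) integer(0) else as.integer(hits)
}

# Try to split one read (already on a fixed strand) into a reference anchor
# and a cassette anchor. The cassette anchor is located from a cassette
# *terminus* k-mer (start k-mer when the cassette occupies the read's 3' end,
# end k-mer when it occupies the 5' end): anchoring at the terminus avoids
# the off-by-one that maximal reference-side extension suffers whenever the
# flank base next to the junction matches the cassette terminus by chance
# (guaranteed to happen at 5 bp target-site duplications at rate ~1/4).
.try_split <- function(read, ref, cass, orientation, k) {
  n <- nchar(read)
  nc <- nchar(cass)
  # configuration A: reference prefix + cassette suffix (cassette 5' terminus)
  key <- substr(cass, 1L, k)
  q <- regexpr(key, read, fixed = TRUE)[1]
  if (q > k) {                       # need >= k reference bases before it
    cass_part <- substr(read, q, n)
    if (cass_part == substr(cass, 1L, n - q + 1L)) {
      anchor <- substr(read, 1L, q - 1L)
      occ <- .count_occurrences(anchor, ref)
      if (length(occ) == 1) {
        s <- occ[1] - 1L             # 0-based anchor start
        return(list(ref_anchor = c(s, s + q - 1L), cassette_side = "right",
                    orientation = orientation, breakpoint = s + q - 1L))
      }
      if (length(occ) >= 2) return("ambiguous")
    }
  }
  # configuration B: cassette prefix (cassette 3' terminus) + reference suffix
  key <- substr(cass, nc - k + 1L, nc)
  q <- regexpr(key, read, fixed = TRUE)[1]
  if (q > 0) {
    j <- q + k - 1L                  # last cassette base in the read
    if (j >= k && n - j >= k) {
      cass_part <- substr(read, 1L, j)
      if (cass_part == substr(cass, nc - j + 1L, nc)) {
        anchor <- substr(read, j + 1L, n)
        occ <- .count_occurrences(anchor, ref)
        if (length(occ) == 1) {
          s <- occ[1] - 1L
          return(list(ref_anchor = c(s, s + (n - j)), cassette_side = "left",
                      orientation = orientation, breakpoint = s))
        }
        if (length(occ) >= 2) return("ambiguous")
      }
    }
  }
  NULL
}

#' Locate the insertion junction in a single read
#'
#' Splits the read into an exact reference anchor and an exact cassette
#' anchor (both at least `min_anchor` long), trying the read and its reverse
#' complement against both cassette strands. Returns `NULL` when no valid
#' split exists or when the reference anchor matches two or more loci
#' (ambiguous).
#'
#' @param read read sequence (character)
#' @param reference a `dip_reference` or character CDS
#' @param cassette a `dip_cassette` or character insert sequence
#' @param min_anchor minimum anchor length on each side (>= 12)
#' @param read_id id stored in the hit
#' @return a `dip_junction` (list with `read_id`, `ref_anchor` as a 0-based
#'   half-open interval, `cassette_side`, `orientation`, `breakpoint`) or
#'   `NULL`
#' @export
find_junction <- function(read, reference, cassette, min_anchor = 15,
                          read_id = NA_character_) {
  .junction_engine(read, .ref_cds(reference), .cassette_nt(cassette),
                   revcomp(.cassette_nt(cassette)), min_anchor, read_id)
}

.junction_engine <- function(read, ref, cass_f, cass_r, min_anchor,
                             read_id) {
  if (min_anchor < 12) stop_invalid("min_anchor must be >= 12")
  if (is.na(read) || nchar(read) < 2 * min_anchor) return(NULL)
  for (seq in c(read, revcomp(read))) {
    for (i in 1:2) {
      hit <- .try_split(seq, ref,
                        if (i == 1) cass_f else cass_r,
                        if (i == 1) "forward" else "reverse",
                        as.integer(min_anchor))
      if (is.character(hit)) return(NULL)   # ambiguous
      if (!is.null(hit)) {
        hit$read_id <- read_id
        class(hit) <- "dip_junction"
        return(hit)
      }
    }
  }
  NULL
}

#' Convert a junction hit to an insertion call
#'
#' The 5-bp target-site duplication flanks the insert on both sides; with the
#' duplication assigned to the reference, an upstream-junction hit
#' (`cassette_side == "right"`) has `nt_pos = breakpoint - 5`, and a
#' downstream-junction hit (`cassette_side == "left"`) has
#' `nt_pos = breakpoint`. Frame is `nt_pos mod 3`; a call is productive iff
#' forward orientation and frame 0, in which case `aa_pos = nt_pos / 3`.
#'
#' @param hit a `dip_junction`
#' @param reference a `dip_reference` or character CDS
#' @return a `dip_call`: list with `read_id`, `nt_pos`, `orientation`,
#'   `frame`, `productive`, `aa_pos`
#' @export
call_insertion <- function(hit, reference) {
  if (is.null(hit)) return(NULL)
  len <- nchar(.ref_cds(reference))
  nt_pos <- if (hit$cassette_side == "right") hit$breakpoint - 5L
            else hit$breakpoint
  if (nt_pos < 0 || nt_pos > len - 5L) {
    stop_invalid("breakpoint within 5 nt of reference end (nt_pos ", nt_pos,
                 " out of [0, ", len - 5L, "])")
  }
  frame <- nt_pos %% 3L
  productive <- hit$orientation == "forward" && frame == 0L
  structure(list(read_id = hit$read_id, nt_pos = as.integer(nt_pos),
                 orientation = hit$orientation, frame = as.integer(frame),
                 productive = productive,
                 aa_pos = if (frame == 0L) nt_pos %/% 3L else NA_integer_),
            class = "dip_call")
}

#' Reconcile the two calls of a read pair
#'
#' When both mates yield a call and the calls agree (same `nt_pos` and
#' orientation), the duplicate call is collapsed to a single call under
#' `policy = "dedupe"`, or the whole pair is discarded under
#' `policy = "drop"` (the stricter reading of removing pairs with duplicate
#' forward/reverse calls). Disagreeing mates are always discarded; a single
#' calling mate is emitted as-is.
#'
#' @param call_r1,call_r2 `dip_call` or `NULL`
#' @param policy `"dedupe"` (default) or `"drop"`
#' @return a `dip_call` or `NULL`
#' @export
reconcile_pair <- function(call_r1, call_r2,
                           policy = c("dedupe", "drop")) {
  policy <- match.arg(policy)
  if (is.null(call_r1)) return(call_r2)
  if (is.null(call_r2)) return(call_r1)
  agree <- call_r1$nt_pos == call_r2$nt_pos &&
    call_r1$orientation == call_r2$orientation
  if (!agree) return(NULL)
  if (policy == "drop") return(NULL)
  call_r1
}

#' Call insertions for a set of read pairs
#'
#' Runs [find_junction()] and [call_insertion()] on both mates of every pair
#' and reconciles them with [reconcile_pair()].
#'
#' @param r1,r2 character vectors of mate sequences (same length); `r2` may
#'   be `NULL` for single-end calling
#' @param reference,cassette as in [find_junction()]
#' @param ids read ids (defaults to index)
#' @param min_anchor minimum anchor length
#' @param policy pair policy, see [reconcile_pair()]
#' @return data frame `read_id`, `nt_pos`, `orientation`, `frame`,
#'   `productive`, `aa_pos` (one row per emitted call)
#' @export
call_reads <- function(r1, r2 = NULL, reference, cassette,
                       ids = as.character(seq_along(r1)), min_anchor = 15,
                       policy = "dedupe") {
  ref <- .ref_cds(reference)
  cass_f <- .cassette_nt(cassette)
  cass_r <- revcomp(cass_f)
  n <- length(r1)
  # preallocated columns; rbind of per-read data frames is quadratic
  o_id <- character(n); o_nt <- integer(n); o_or <- character(n)
  o_fr <- integer(n); o_pr <- logical(n); o_aa <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    h1 <- .junction_engine(r1[i], ref, cass_f, cass_r, min_anchor, ids[i])
    c1 <- if (is.null(h1)) NULL else call_insertion(h1, ref)
    c2 <- NULL
    if (!is.null(r2)) {
      h2 <- .junction_engine(r2[i], ref, cass_f, cass_r, min_anchor, ids[i])
      c2 <- if (is.null(h2)) NULL else call_insertion(h2, ref)
    }
    cc <- reconcile_pair(c1, c2, policy)
    if (!is.null(cc)) {
      m <- m + 1L
      o_id[m] <- cc$read_id; o_nt[m] <- cc$nt_pos
      o_or[m] <- cc$orientation; o_fr[m] <- cc$frame
      o_pr[m] <- cc$productive
      o_aa[m] <- if (is.na(cc$aa_pos)) NA_integer_ else cc$aa_pos
    }
  }
  keep <- seq_len(m)
  data.frame(read_id = o_id[keep], nt_pos = o_nt[keep],
             orientation = o_or[keep], frame = o_fr[keep],
             productive = o_pr[keep], aa_pos = o_aa[keep],
             stringsAsFactors = FALSE)
}

#' Tally insertion calls into a per-residue count table
#'
#' @param calls data frame from [call_reads()] (or compatible)
#' @param n_residues number of codons of the reference; the count grid spans
#'   `aa_pos` 0 to `n_residues - 2`
#' @param productive_only drop non-productive calls (default TRUE)
#' @param pool,replicate,domain metadata stored on the table
#' @return a `dip_counts` with `t` equal to the number of tallied calls
#' @export
tally <- function(calls, n_residues, productive_only = TRUE,
                  pool = NA_character_, replicate = NA_integer_,
                  domain = NA_character_) {
  if (productive_only) calls <- calls[calls$productive, , drop = FALSE]
  grid <- 0:(n_residues - 2L)
  cnt <- integer(length(grid))
  if (nrow(calls) > 0) {
    tb <- table(factor(calls$aa_pos, levels = grid))
    cnt <- as.integer(tb)
  }
  dip_counts(grid, cnt, pool = pool, replicate = replicate, domain = domain)
}

#' Write / read a plaintext insertion-call table
#'
#' Tab-separated with a header; coordinates are 0-based (`nt_pos`), residue
#' indices 1-based (`aa_pos`), as stated in the header comment line.
#'
#' @param calls data frame from [call_reads()]
#' @param path file path
#' @return the path (write) or the calls data frame (read)
#' @export
write_calls <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# nt_pos: 0-based; aa_pos: 1-based (0 = before residue 1)", con)
  utils::write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
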