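#' Count global in/out passage events
#'
#' A global "in" event is a complete solvent -> protein -> geminate passage;
#' a global "out" event the reverse. Oscillations that do not complete the
#' passage (geminate <-> protein, or protein <-> solvent) are not counted.
#'
#' Each ligand is tracked by an anchor in `{S, G}` initialized to its first
#' non-`P` state: entering `G` while anchored at `S` records an in event and
#' re-anchors at `G`; entering `S` while anchored at `G` records an out
#' event and re-anchors at `S`. A ligand that never leaves `P` contributes
#' no events. The number of completed cycles is `min(n_in, n_out)` per
#' ligand, summed. Geminate residence accumulates as (number of `G` frames)
#' x `dt` over all ligands, the half-open entry-counted convention.
#'
#' @param sm a [state_matrix()].
#' @return object of class `event_summary`: counts `n_in`, `n_out`,
#'   `n_in_out`, times `t_geminate_ns`, `t_sim_ns`, per-ligand table
#'   `per_ligand` (`ligand`, `n_in`, `n_out`, `n_in_out`, `t_geminate_ns`),
#'   completed-cycle records `records` (`ligand`, `frame_in`, `frame_out`),
#'   `n_ligands`, `dt`.
#' @export
count_global_events <- function(sm) {
  stopifnot(inherits(sm, "state_matrix"))
  states <- sm$states
  if (nrow(states) == 0L) stop("empty state matrix", call. = FALSE)
  nl <- ncol(states)
  per <- data.frame(ligand = sm$ligand_ids, n_in = 0L, n_out = 0L,
                    n_in_out = 0L, t_geminate_ns = 0,
                    stringsAsFactors = FALSE)
  recs <- list()
  for (l in seq_len(nl)) {
    col <- states[, l]
    r <- rle(col)
    vals <- r$values
    starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    anchor <- NA_character_
    n_in <- 0L; n_out <- 0L
    open_in_frame <- NA_integer_
    for (i in seq_along(vals)) {
      v <- vals[i]
      if (is.na(anchor)) {
        if (v != "P") anchor <- v
        next
      }
      if (v == "G" && anchor == "S") {
        n_in <- n_in + 1L
        anchor <- "G"
        open_in_frame <- starts[i]
      } else if (v == "S" && anchor == "G") {
        n_out <- n_out + 1L
        anchor <- "S"
        if (!is.na(open_in_frame)) {
          recs[[length(recs) + 1L]] <- c(l, open_in_frame, starts[i])
          open_in_frame <- NA_integer_
        }
      }
    }
    per$n_in[l] <- n_in
    per$n_out[l] <- n_out
    per$n_in_out[l] <- min(n_in, n_out)
    per$t_geminate_ns[l] <- sum(col == "G") * sm$dt / 1000
  }
  records <- if (length(recs)) {
    as.data.frame(do.call(rbind, recs)) |>
      stats::setNames(c("ligand", "frame_in", "frame_out"))
  } else {
    data.frame(ligand = integer(), frame_in = integer(), frame_out = integer())
  }
  structure(
    list(n_in = sum(per$n_in), n_out = sum(per$n_out),
         n_in_out = sum(per$n_in_out),
         t_geminate_ns = sum(per$t_geminate_ns),
         t_sim_ns = nrow(states) * sm$dt / 1000,
         per_ligand = per, records = records,
         n_ligands = nl, dt = sm$dt),
    class = "event_summary"
  )
}

#' @export
print.event_summary <- function(x, ...) {
  cat(sprintf(paste0("event_summary: %d in / %d out (%d completed cycles), ",
                     "t_sim = %.4g ns, geminate residence = %.4g ns over %d ligands\n"),
              x$n_in, x$n_out, x$n_in_out, x$t_sim_ns, x$t_geminate_ns,
              x$n_ligands))
  if (x$n_in_out < 5) {
    cat("  note: fewer than 5 completed cycles; sampling is low\n")
  }
  invisible(x)
}
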