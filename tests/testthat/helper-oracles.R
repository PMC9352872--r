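# Independent oracles used to cross-check the implementation. These are
# deliberately naive (day-set enumeration, per-event walks) and share no code
# with the package internals.

# covered-day set of closed spans
oracle_covered_days <- function(starts, ends) {
  if (!length(starts)) return(integer())
  sort(unique(unlist(mapply(function(s, e) seq(as.integer(s), as.integer(e)),
                            starts, ends, SIMPLIFY = FALSE))))
}

# single-pass line construction oracle: walks the event stream date by date,
# maintaining explicit state; used to verify build_lines on hand and random
# cases for a single patient
oracle_lines <- function(fills, terminals, obs_end, gap = 90) {
  # fills: data.frame(date, drug, supply); terminals: data.frame(date, kind).
  # All dates must share one numeric day scale (offsets or Date, not mixed).
  to_days <- function(x) if (inherits(x, "Date")) as.integer(x) else as.integer(x)
  obs_end <- to_days(obs_end)
  fills$date <- to_days(fills$date)
  fills <- fills[order(fills$date, fills$drug), , drop = FALSE]
  fills <- fills[fills$date <= obs_end, , drop = FALSE]
  if (!nrow(fills)) return(NULL)
  tdate <- NA_integer_; tkind <- NA_character_
  if (nrow(terminals)) {
    terminals$date <- to_days(terminals$date)
    terminals <- terminals[terminals$date <= obs_end &
                             terminals$date >= min(fills$date), , drop = FALSE]
    if (nrow(terminals)) {
      pr <- ifelse(terminals$kind == "hsct", 1L, 2L)
      o <- order(terminals$date, pr)
      tdate <- terminals$date[o[1]]; tkind <- terminals$kind[o[1]]
    }
  }
  if (!is.na(tdate)) fills <- fills[fills$date < tdate, , drop = FALSE]
  if (!nrow(fills)) return(NULL)

  out <- list()
  cur <- NULL
  pick <- function(rows) {
    rows <- rows[order(-rows$supply, rows$drug), , drop = FALSE]
    rows$drug[1]
  }
  for (dte in sort(unique(fills$date))) {
    here <- fills[fills$date == dte, , drop = FALSE]
    if (is.null(cur)) {
      dgr <- pick(here)
      mine <- here[here$drug == dgr, , drop = FALSE]
      cur <- list(drug = dgr, start = dte, se = max(mine$date + mine$supply),
                  nf = nrow(mine), ni = 0L)
      next
    }
    mine <- here[here$drug == cur$drug, , drop = FALSE]
    other <- here[here$drug != cur$drug, , drop = FALSE]
    if (nrow(mine)) {
      if (dte - cur$se >= gap) cur$ni <- cur$ni + 1L
      cur$nf <- cur$nf + nrow(mine)
      cur$se <- max(cur$se, mine$date + mine$supply)
    }
    if (nrow(other)) {
      out[[length(out) + 1]] <- data.frame(
        drug = cur$drug, start = cur$start, end = dte, sup_end = cur$se,
        event = "switch", n_fills = cur$nf, interruptions = cur$ni)
      dgr <- pick(other)
      mine <- other[other$drug == dgr, , drop = FALSE]
      cur <- list(drug = dgr, start = dte, se = max(mine$date + mine$supply),
                  nf = nrow(mine), ni = 0L)
    }
  }
  if (!is.na(tdate)) {
    out[[length(out) + 1]] <- data.frame(
      drug = cur$drug, start = cur$start, end = tdate, sup_end = cur$se,
      event = tkind, n_fills = cur$nf, interruptions = cur$ni)
  } else if (obs_end - cur$se >= gap) {
    out[[length(out) + 1]] <- data.frame(
      drug = cur$drug, start = cur$start, end = cur$se, sup_end = cur$se,
      event = "discontinuation", n_fills = cur$nf, interruptions = cur$ni)
  } else {
    out[[length(out) + 1]] <- data.frame(
      drug = cur$drug, start = cur$start, end = obs_end, sup_end = cur$se,
      event = "censored", n_fills = cur$nf, interruptions = cur$ni)
  }
  do.call(rbind, out)
}
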