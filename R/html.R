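# Self-contained HTML overview: run summary, a sortable results table, and
# a per-precursor detail view with each reported isomiR rendered in
# register under its expanded precursor, the mature reference span(s)
# marked. Plain generated markup with a little inline CSS/JS; no external
# resources, so the file opens offline in any browser.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write the HTML overview
#'
#' @param profile An `isomir_profile`.
#' @param bundle The matching `isomir_bundle`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_html <- function(profile, bundle, path) {
  rows <- assemble_rows(profile, bundle)
  s <- profile$summary
  head <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"><title>isomiR profile</title>",
    "<style>",
    "body{font-family:sans-serif;margin:2em}",
    "table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:2px 6px;font-size:90%}",
    "th{cursor:pointer;background:#eee}",
    "pre{font-family:monospace;background:#f7f7f7;padding:4px}",
    ".iso{color:#080}.mature{font-weight:bold;text-decoration:underline}",
    "</style>",
    "<script>",
    "function sortTable(t,c){var tb=t.tBodies[0],r=Array.from(tb.rows);",
    "var num=r.every(function(x){return !isNaN(parseFloat(x.cells[c].innerText))});",
    "r.sort(function(a,b){var x=a.cells[c].innerText,y=b.cells[c].innerText;",
    "return num?parseFloat(x)-parseFloat(y):x.localeCompare(y);});",
    "r.forEach(function(x){tb.appendChild(x);});}",
    "</script></head><body>",
    "<h1>isomiR profile</h1>")
  smry <- c(
    "<h2>Run summary</h2><table><tbody>",
    sprintf("<tr><td>%s</td><td>%s</td></tr>",
            c("Total reads", "Mapped reads", "Exclusive reads",
              "Ambiguous reads", "Variant reads", "NTA-rescued reads",
              "Unmapped reads"),
            c(s$total_reads, s$mapped_reads,
              sprintf("%d (%.2f%%)", s$exclusive_reads, s$pct_exclusive),
              sprintf("%d (%.2f%%)", s$ambiguous_reads, s$pct_ambiguous),
              sprintf("%d (%.2f%%)", s$variant_reads, s$pct_variant),
              sprintf("%d (%.2f%%)", s$nta_reads, s$pct_nta),
              sprintf("%d (%.2f%%)", s$unmapped_reads, s$pct_unmapped))),
    "</tbody></table>")
  tab <- character(0)
  if (nrow(rows) > 0L) {
    cols <- c("plate", "seq", "category", "type", "exclusive",
              "repeat_classes", "placements", "offset_labels", "variant_ids",
              "count", "rpm_all", "rpm_mapped")
    header <- paste0(sprintf(
      "<th onclick=\"sortTable(this.closest('table'),%d)\">%s</th>",
      seq_along(cols) - 1L, cols), collapse = "")
    body <- vapply(seq_len(nrow(rows)), function(i) {
      vals <- vapply(cols, function(cl) {
        v <- rows[[cl]][i]
        if (is.double(v)) sprintf("%.2f", v) else html_escape(as.character(v))
      }, character(1))
      paste0("<tr>", paste0("<td>", vals, "</td>", collapse = ""), "</tr>")
    }, character(1))
    tab <- c("<h2>Reported isomiRs</h2>",
             "<table><thead><tr>", header, "</tr></thead><tbody>",
             body, "</tbody></table>")
  }
  detail <- precursor_detail_html(profile, bundle)
  writeLines(c(head, smry, tab, detail, "</body></html>"), path)
  invisible(path)
}

# For each precursor hosting at least one reported isomiR: the expanded
# sequence, the mature span(s) of each database marked beneath it, and each
# reported isomiR aligned at its placement.
precursor_detail_html <- function(profile, bundle) {
  hits <- profile$hits
  if (nrow(hits) == 0L) return(character(0))
  plc <- bind_rows(bundle$placements, bundle$variant_placements)
  lk <- ifelse(hits$category == "nta", hits$templated_core, hits$seq)
  plc <- plc |> filter(.data$seq %in% lk)
  if (nrow(plc) == 0L) return(character(0))
  out <- c("<h2>Per-precursor detail</h2>")
  for (nm in sort(unique(plc$precursor))) {
    e <- bundle$expanded[bundle$expanded$name == nm, ]
    lines <- sprintf("%-18s %s", html_escape(nm), e$seq)
    mt <- bundle$matures |> filter(.data$precursor == nm)
    for (j in seq_len(nrow(mt))) {
      m_start <- mt$offset[j] + e$pad5
      mark <- paste0(strrep(" ", m_start - 1L),
                     "<span class=\"mature\">",
                     substr(e$seq, m_start, m_start + mt$length[j] - 1L),
                     "</span>")
      lines <- c(lines, sprintf("%-18s %s",
                                html_escape(paste0(mt$name[j], " (", e$db, ")")),
                                mark))
    }
    pp <- plc |> filter(.data$precursor == nm) |> arrange(.data$start)
    for (j in seq_len(nrow(pp))) {
      h <- hits[lk == pp$seq[j], ][1, ]
      shown <- paste0(strrep(" ", pp$start[j] - 1L),
                      "<span class=\"iso\">", pp$seq[j], "</span>",
                      if (h$category == "nta") html_escape(h$tail) else "")
      lines <- c(lines, sprintf("%-18s %s", html_escape(h$plate), shown))
    }
    out <- c(out, sprintf("<h3>%s</h3><pre>", html_escape(nm)),
             lines, "</pre>")
  }
  out
}
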