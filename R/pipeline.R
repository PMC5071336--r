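#' Read and validate a study manifest
#'
#' The manifest drives a full pipeline run. One row per recording session:
#' \code{file} (WAV recording or pre-coded sequences CSV), \code{kind}
#' ("audio" or "sequences"), \code{animal_id}, \code{group} (e.g. genotype),
#' \code{context} (e.g. UF/LF/AF/AM), \code{session_minutes}.
#'
#' @param path manifest CSV path.
#' @param checkFiles verify every referenced file exists (default TRUE).
#' @return validated data.frame.
#' @export
readManifest <- function(path, checkFiles = TRUE) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("file", "kind", "animal_id", "group", "context",
              "session_minutes")
  missing <- setdiff(needed, names(man))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "))
  if (!all(man$kind %in% c("audio", "sequences")))
    stop("manifest kind must be 'audio' or 'sequences'")
  key <- paste(man$animal_id, man$context)
  if (anyDuplicated(key))
    stop("duplicate (animal_id, context) session(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (checkFiles) {
    bad <- !file.exists(man$file)
    if (any(bad))
      stop("manifest file(s) not found: ",
           paste(man$file[bad], collapse = ", "))
  }
  man
}

## SyntaxTestResult -> plain list for JSON serialization
resultToList <- function(result) {
  cells <- transitionCells()
  lp <- result@localP[cbind(cells$from, cells$to)]
  names(lp) <- paste0(cells$from, "_", cells$to)
  list(comparison = result@comparison,
       tau = result@tau, n_permutations = result@nPerm,
       seed = result@seed,
       local_p = as.list(lp),
       to_p = as.list(result@toP),
       from_p = as.list(result@fromP),
       global_p = result@globalP,
       to_p_adjusted = as.list(result@toPAdj),
       from_p_adjusted = as.list(result@fromPAdj))
}

#' Write a sampled synthetic cohort as a sequences CSV
#'
#' Flattens \code{\link{sampleCohort}} output into the sequences-CSV schema a
#' pipeline run consumes.
#'
#' @param cohort result of \code{\link{sampleCohort}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeCohortSequences <- function(cohort, path) {
  rows <- list()
  for (g in names(cohort$corpora))
    for (a in names(cohort$corpora[[g]]))
      for (ctx in names(cohort$corpora[[g]][[a]])) {
        coded <- cohort$corpora[[g]][[a]][[ctx]]
        if (!length(coded)) next
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = a, group = g, context = ctx,
          bout_index = seq_along(coded), coded_string = coded,
          n_syllables = nchar(coded))
      }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

## events table for one session -> sequences + summary rows
sessionTables <- function(events, animalId, group, context, sessionMinutes,
                          breakMs) {
  events <- events[events$label %in% setdiff(USV_STATES, "X"), , drop = FALSE]
  events <- segmentIntoSequences(events, breakMs)
  coded <- letterCode(events)
  seqs <- if (length(coded)) {
    starts <- vapply(split(events$onset_s, events$bout_index), min,
                     numeric(1L))
    ends <- vapply(split(events$offset_s, events$bout_index), max,
                   numeric(1L))
    data.frame(animal_id = animalId, group = group, context = context,
               bout_index = seq_along(coded), coded_string = unname(coded),
               n_syllables = nchar(unname(coded)),
               start_s = unname(starts), end_s = unname(ends))
  } else NULL
  summary <- sessionSummary(events, sessionMinutes, animalId, context)
  summary$group <- group
  list(sequences = seqs, summary = summary)
}

#' Run the full detection / sequencing / syntax pipeline
#'
#' Orchestrates every stage over a study manifest: syllable detection on
#' audio sessions, sequence segmentation and letter coding, per-session
#' summaries, the requested syntax comparisons (paired within group across
#' contexts, two-sample across groups within context), syntax diagrams, and
#' a machine-readable run report. All intermediate tables are written to
#' \code{outDir}; the run is deterministic given \code{seed}.
#'
#' @param manifest data.frame from \code{\link{readManifest}} (or equivalent).
#' @param outDir output directory (created if needed).
#' @param comparisons list of comparison specs: each a list with either
#'   \code{type = "two-sample"}, \code{group1}, \code{group2}, \code{context},
#'   or \code{type = "paired"}, \code{group}, \code{context1},
#'   \code{context2}. Defaults to every between-group comparison per context
#'   and every within-group context pair.
#' @param config \code{\link{sonogramConfig}} for the detection stage.
#' @param breakMs sequence-break threshold (ms).
#' @param tau,nPerm truncated-product and permutation settings of
#'   \code{\link{syntaxTest}}.
#' @param seed integer master seed; comparison c uses \code{seed + c}.
#' @param cutoff diagram probability cutoff.
#' @return (invisibly) list with the sequences and summaries data.frames and
#'   the \linkS4class{SyntaxTestResult} objects, named by comparison.
#' @export
runPipeline <- function(manifest, outDir, comparisons = NULL,
                        config = sonogramConfig(), breakMs = 250,
                        tau = 0.05, nPerm = 1000L, seed = 1L,
                        cutoff = 0.05) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("syllables", "syntax", "diagrams"))
    dir.create(file.path(outDir, d), showWarnings = FALSE)
  groups <- unique(manifest$group)
  contexts <- unique(manifest$context)

  ## default comparison plan mirrors the two-genotype, multi-context design
  if (is.null(comparisons)) {
    comparisons <- list()
    if (length(groups) >= 2L)
      for (i in seq_along(groups)[-1L]) for (ctx in contexts)
        comparisons[[length(comparisons) + 1L]] <- list(
          type = "two-sample", group1 = groups[1L], group2 = groups[i],
          context = ctx)
    if (length(contexts) >= 2L)
      for (g in groups)
        for (i in seq_len(length(contexts) - 1L))
          for (j in seq.int(i + 1L, length(contexts)))
            comparisons[[length(comparisons) + 1L]] <- list(
              type = "paired", group = g, context1 = contexts[i],
              context2 = contexts[j])
  }
  for (cmp in comparisons) {
    want <- if (cmp$type == "two-sample") c(cmp$group1, cmp$group2)
    else cmp$group
    absent <- setdiff(want, groups)
    if (length(absent))
      stop("comparison requests group(s) with no sessions: ",
           paste(absent, collapse = ", "))
  }

  ## stage 1 + 2: per-session events -> sequences + summaries
  allSeqs <- list(); allSums <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    if (row$kind == "audio") {
      au <- readWav(row$file)
      events <- detectSyllableEvents(au$wave, au$rate, config,
                                     file = row$file)
      utils::write.csv(events, file.path(
        outDir, "syllables",
        paste0(row$animal_id, "_", row$context, ".csv")), row.names = FALSE)
      tabs <- sessionTables(events, row$animal_id, row$group, row$context,
                            row$session_minutes, breakMs)
    } else {
      seqs <- utils::read.csv(row$file, stringsAsFactors = FALSE)
      seqs <- seqs[seqs$animal_id == row$animal_id &
                     seqs$context == row$context, , drop = FALSE]
      coded <- seqs$coded_string
      tabs <- list(
        sequences = if (nrow(seqs)) data.frame(
          animal_id = row$animal_id, group = row$group,
          context = row$context, bout_index = seq_along(coded),
          coded_string = coded, n_syllables = nchar(coded),
          start_s = NA_real_, end_s = NA_real_) else NULL,
        summary = {
          s <- data.frame(
            animal_id = row$animal_id, context = row$context,
            session_minutes = row$session_minutes,
            total_syllables = sum(nchar(coded)),
            syllable_rate = sum(nchar(coded)) / row$session_minutes,
            prop_s = NA_real_, prop_d = NA_real_, prop_u = NA_real_,
            prop_m = NA_real_, n_sequences = length(coded),
            mean_seq_length = if (length(coded))
              sum(nchar(coded)) / length(coded) else NA_real_,
            complex_simple_ratio = complexSimpleRatio(coded)$ratio)
          if (sum(nchar(coded)) > 0) {
            labs <- unlist(parseCoded(coded))
            tab <- table(factor(labs, levels = c("s", "d", "u", "m")))
            s[, c("prop_s", "prop_d", "prop_u", "prop_m")] <-
              as.list(as.numeric(tab) / length(labs))
          }
          s$group <- row$group
          s
        })
    }
    if (!is.null(tabs$sequences))
      allSeqs[[length(allSeqs) + 1L]] <- tabs$sequences
    allSums[[length(allSums) + 1L]] <- tabs$summary
  }
  sequences <- do.call(rbind, allSeqs)
  summaries <- do.call(rbind, allSums)
  utils::write.csv(sequences, file.path(outDir, "sequences.csv"),
                   row.names = FALSE)
  utils::write.csv(summaries, file.path(outDir, "summaries.csv"),
                   row.names = FALSE)

  corpusOf <- function(group, context) {
    sel <- sequences$group == group & sequences$context == context
    split(sequences$coded_string[sel], sequences$animal_id[sel])
  }

  ## stage 3: syntax comparisons
  results <- list(); report <- list()
  for (ci in seq_along(comparisons)) {
    cmp <- comparisons[[ci]]
    cmpSeed <- seed + ci
    if (cmp$type == "two-sample") {
      m1 <- animalProbabilities(corpusOf(cmp$group1, cmp$context),
                                cmp$context)
      m2 <- animalProbabilities(corpusOf(cmp$group2, cmp$context),
                                cmp$context)
      nm <- paste0(cmp$group1, "_vs_", cmp$group2, "_", cmp$context)
    } else {
      c1 <- corpusOf(cmp$group, cmp$context1)
      c2 <- corpusOf(cmp$group, cmp$context2)
      shared <- intersect(names(c1), names(c2))
      m1 <- animalProbabilities(c1[shared], cmp$context1)
      m2 <- animalProbabilities(c2[shared], cmp$context2)
      nm <- paste0(cmp$group, "_", cmp$context1, "_vs_", cmp$context2)
    }
    res <- syntaxTest(m1, m2, type = cmp$type, tau = tau, nPerm = nPerm,
                      seed = cmpSeed)
    results[[nm]] <- res
    jsonlite::write_json(resultToList(res),
                         file.path(outDir, "syntax", paste0(nm, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(heatmapTable(res),
                     file.path(outDir, "syntax", paste0(nm, "_heatmap.csv")))
    report[[length(report) + 1L]] <- c(cmp, list(
      name = nm, global_p = globalP(res), seed = cmpSeed))
    message("comparison ", nm, ": global p = ",
            format.pval(globalP(res), digits = 4))
  }

  ## stage 4: group-context diagrams
  for (g in groups) for (ctx in contexts) {
    corp <- corpusOf(g, ctx)
    if (!length(corp)) next
    gm <- groupMeanProbabilities(animalProbabilities(corp, ctx))$mean
    writeLines(syntaxDot(gm, cutoff = cutoff,
                         name = paste0(g, "_", ctx)),
               file.path(outDir, "diagrams", paste0(g, "_", ctx, ".dot")))
  }

  jsonlite::write_json(
    list(seed = seed, tau = tau, n_permutations = nPerm,
         break_ms = breakMs, comparisons = report),
    file.path(outDir, "run_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sequences = sequences, summaries = summaries,
                 results = results))
}
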