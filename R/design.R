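#' Configuration for the event-related stimulus design
#'
#' Validated parameter list for \code{\link{generateDesign}}. Defaults encode
#' the study conditions: 14 participants, 8 runs of 4 blocks, 18 trials per
#' block, a 4 s instruction period, 3.5 s image presentations, jittered
#' inter-stimulus intervals drawn from \{0.5, 2.5, 4.5\} s with every block
#' constrained to last exactly 96 s, 16 images per category-by-quality cell
#' per task (144 unique images per task), each presented twice with at least
#' one intervening trial between repetitions.
#'
#' Timing values are handled at 0.1 s resolution so the block-duration
#' identity is exact, not float-approximate.
#'
#' @param nParticipants number of participants.
#' @param nRuns number of scanning runs.
#' @param blocksPerRun task blocks per run (2 or 4; task order is
#'   counterbalanced by run parity).
#' @param trialsPerBlock image presentations per block.
#' @param instructionS instruction period at block start, seconds.
#' @param imageDurationS image presentation duration, seconds.
#' @param isiMenuS permitted inter-stimulus intervals, seconds.
#' @param blockTotalS exact total block duration, seconds.
#' @param imagesPerCell unique images per category x quality cell per task.
#' @param presentationsPerImage presentations of each image within its task.
#' @param minLag minimum number of intervening trials between two
#'   presentations of the same image.
#' @param fixationStartS fixation before the first block of each run, seconds.
#' @param sharedOrder if TRUE (default) every participant sees the same
#'   sequence and timing; if FALSE each participant gets an independent draw.
#' @param seed integer seed controlling all randomization.
#' @return a validated configuration list (class \code{"DesignConfig"}).
#' @export
designConfig <- function(nParticipants = 14L, nRuns = 8L, blocksPerRun = 4L,
                         trialsPerBlock = 18L, instructionS = 4,
                         imageDurationS = 3.5, isiMenuS = c(0.5, 2.5, 4.5),
                         blockTotalS = 96, imagesPerCell = 16L,
                         presentationsPerImage = 2L, minLag = 1L,
                         fixationStartS = 12, sharedOrder = TRUE, seed = 1L) {
  cfg <- list(nParticipants = as.integer(nParticipants),
              nRuns = as.integer(nRuns),
              blocksPerRun = as.integer(blocksPerRun),
              trialsPerBlock = as.integer(trialsPerBlock),
              instructionS = instructionS, imageDurationS = imageDurationS,
              isiMenuS = sort(unique(isiMenuS)), blockTotalS = blockTotalS,
              imagesPerCell = as.integer(imagesPerCell),
              presentationsPerImage = as.integer(presentationsPerImage),
              minLag = as.integer(minLag), fixationStartS = fixationStartS,
              sharedOrder = isTRUE(sharedOrder), seed = as.integer(seed))
  if (cfg$nParticipants < 1L) stop("need at least one participant")
  if (!cfg$blocksPerRun %in% c(2L, 4L))
    stop("blocksPerRun must be 2 or 4 (palindromic task counterbalancing)")
  if (cfg$nRuns %% 2L != 0L)
    stop("nRuns must be even so task order counterbalances across run parity")
  isi_target <- cfg$blockTotalS - cfg$instructionS -
    cfg$trialsPerBlock * cfg$imageDurationS
  if (isi_target < 0)
    stop("block too short for instruction period plus image presentations")
  cfg$isiTargetS <- isi_target
  trials_per_task_design <- 9L * cfg$imagesPerCell * cfg$presentationsPerImage
  blocks_per_task <- cfg$nRuns * cfg$blocksPerRun %/% 2L
  if (trials_per_task_design != blocks_per_task * cfg$trialsPerBlock)
    stop(sprintf(paste("design infeasible: 9 cells x %d images x %d",
                       "presentations = %d trials per task, but %d blocks x",
                       "%d trials provide %d"),
                 cfg$imagesPerCell, cfg$presentationsPerImage,
                 trials_per_task_design, blocks_per_task, cfg$trialsPerBlock,
                 blocks_per_task * cfg$trialsPerBlock))
  if ((cfg$imagesPerCell * cfg$presentationsPerImage) %% cfg$nRuns != 0L)
    stop("imagesPerCell x presentationsPerImage must divide evenly over runs (cell counterbalancing)")
  class(cfg) <- "DesignConfig"
  cfg
}

.toTenths <- function(x) {
  v <- round(x * 10)
  if (max(abs(x * 10 - v)) > 1e-6)
    stop("timing values must be multiples of 0.1 s")
  as.integer(v)
}

#' Solve an exact-sum inter-stimulus-interval schedule
#'
#' Finds all multisets of \code{n} intervals from \code{menu} whose sum is
#' exactly \code{targetSum} (working in integer tenths of a second), samples
#' one uniformly, and returns it in uniformly shuffled order.
#'
#' @param n number of intervals to schedule.
#' @param menu permitted interval values, seconds (multiples of 0.1 s).
#' @param targetSum required exact sum, seconds.
#' @param seed optional integer seed; NULL uses the current RNG stream.
#' @return numeric vector of \code{n} intervals summing exactly to
#'   \code{targetSum}.
#' @examples
#' s <- solveIsiSchedule(18, c(0.5, 2.5, 4.5), 29, seed = 1)
#' sum(s)  # exactly 29
#' @export
solveIsiSchedule <- function(n, menu, targetSum, seed = NULL) {
  n <- as.integer(n)
  stopifnot(n >= 1L, length(menu) >= 1L)
  menu <- sort(unique(menu))
  mt <- .toTenths(menu)
  tt <- .toTenths(targetSum)

  # enumerate count vectors (c1..cm), sum ci = n, sum ci*mt_i = tt
  sols <- list()
  recurse <- function(i, left_n, left_sum, counts) {
    if (i == length(mt)) {
      if (left_sum == left_n * mt[i])
        sols[[length(sols) + 1L]] <<- c(counts, left_n)
      return(invisible(NULL))
    }
    for (ci in 0:left_n) {
      rest <- left_sum - ci * mt[i]
      rem <- left_n - ci
      # bound the remaining sum by the remaining menu extremes
      if (rest < rem * min(mt[(i + 1):length(mt)])) next
      if (rest > rem * max(mt[(i + 1):length(mt)])) next
      recurse(i + 1L, rem, rest, c(counts, ci))
    }
  }
  if (length(mt) == 1L) {
    if (n * mt[1] == tt) sols[[1]] <- n
  } else {
    recurse(1L, n, tt, integer(0))
  }
  if (!length(sols))
    stop(sprintf(paste("no schedule of %d intervals from {%s} sums to %g s",
                       "(closest achievable bounds: [%g, %g] s)"),
                 n, paste(menu, collapse = ", "), targetSum,
                 n * min(menu), n * max(menu)))
  withSeed(seed, {
    counts <- sols[[sample.int(length(sols), 1L)]]
    sample(rep(menu, times = counts))
  })
}

#' Constrained shuffle with a minimum repetition lag
#'
#' Randomized backtracking permutation of a multiset such that any two
#' occurrences of the same item are separated by at least \code{minLag}
#' intervening elements. Provably infeasible inputs error immediately; an
#' exhausted search (no valid arrangement) also errors rather than looping.
#'
#' @param items vector possibly containing duplicates.
#' @param minLag required number of intervening elements between repeats.
#' @param seed optional integer seed; NULL uses the current RNG stream.
#' @return a permutation of \code{items} satisfying the lag constraint.
#' @examples
#' shuffleWithMinLag(rep(letters[1:3], 2), minLag = 1, seed = 1)
#' @export
shuffleWithMinLag <- function(items, minLag = 1L, seed = NULL) {
  n <- length(items)
  minLag <- as.integer(minLag)
  if (n == 0L) return(items)
  tab <- table(items)
  max_mult <- max(tab)
  if ((max_mult - 1L) * (minLag + 1L) + 1L > n)
    stop(sprintf(paste("infeasible: item '%s' occurs %d times but only %d",
                       "positions exist for lag %d"),
                 names(tab)[which.max(tab)], max_mult, n, minLag))
  uniq <- names(tab)
  counts <- as.integer(tab)
  withSeed(seed, {
    out <- integer(n)          # indices into uniq
    last_pos <- rep(-1e9, length(uniq))
    solve_pos <- function(pos) {
      if (pos > n) return(TRUE)
      cand <- which(counts > 0L & (pos - last_pos) > minLag)
      if (!length(cand)) return(FALSE)
      for (u in cand[sample.int(length(cand))]) {
        counts[u] <<- counts[u] - 1L
        prev <- last_pos[u]; last_pos[u] <<- pos
        out[pos] <<- u
        if (solve_pos(pos + 1L)) return(TRUE)
        counts[u] <<- counts[u] + 1L
        last_pos[u] <<- prev
      }
      FALSE
    }
    if (!solve_pos(1L))
      stop("no arrangement satisfies the minimum-lag constraint")
    # map unique labels back to representative values, preserving type
    rep_vals <- items[match(uniq, as.character(items))]
    rep_vals[out]
  })
}

.imageCatalog <- function(task, imagesPerCell) {
  cells <- expand.grid(category = categoryLevels(), quality = qualityLevels(),
                       stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(image_id = sprintf("%s_%s_%s_%02d", task, cells$category[i],
                                  cells$quality[i], seq_len(imagesPerCell)),
               category = cells$category[i], quality = cells$quality[i],
               task = task, stringsAsFactors = FALSE)
  }))
}

.participantTrials <- function(cfg) {
  # Per task: deal every category x quality cell's presentations evenly
  # across runs (cell counterbalancing across runs), then order each run's
  # items with the repetition-lag backtracking shuffle. The lag constraint
  # is also enforced across run boundaries within the task sequence.
  seqs <- lapply(c("QA", "CC"), function(task) {
    cat_tab <- .imageCatalog(task, cfg$imagesPerCell)
    per_run <- rep(list(character(0)), cfg$nRuns)
    cells <- split(cat_tab$image_id,
                   paste(cat_tab$category, cat_tab$quality))
    for (cell_ids in cells) {
      copies <- sample(rep(cell_ids, times = cfg$presentationsPerImage))
      run_seq <- rep(sample.int(cfg$nRuns),
                     length.out = length(copies))
      for (i in seq_along(copies))
        per_run[[run_seq[i]]] <- c(per_run[[run_seq[i]]], copies[i])
    }
    ord <- character(0)
    for (r in seq_len(cfg$nRuns)) {
      ok <- FALSE
      for (try in 1:100) {
        cand <- shuffleWithMinLag(per_run[[r]], cfg$minLag)
        tail_prev <- utils::tail(ord, cfg$minLag)
        if (!length(tail_prev) ||
            !any(utils::head(cand, cfg$minLag) %in% tail_prev)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not satisfy the lag constraint across runs")
      ord <- c(ord, cand)
    }
    rep_idx <- stats::ave(seq_along(ord), ord, FUN = seq_along)
    data.frame(image_id = ord,
               category = cat_tab$category[match(ord, cat_tab$image_id)],
               quality = cat_tab$quality[match(ord, cat_tab$image_id)],
               task = task, repetition = as.integer(rep_idx),
               stringsAsFactors = FALSE)
  })
  names(seqs) <- c("QA", "CC")
  task_cursor <- c(QA = 0L, CC = 0L)

  half <- cfg$blocksPerRun %/% 2L
  base <- rep(c("QA", "CC"), length.out = half)
  odd_pattern <- if (half == 1L) c("QA", "CC") else c(base, rev(base))
  swap <- function(x) ifelse(x == "QA", "CC", "QA")

  rows <- vector("list", cfg$nRuns * cfg$blocksPerRun)
  ri <- 0L
  for (run in seq_len(cfg$nRuns)) {
    pattern <- if (run %% 2L == 1L) odd_pattern else swap(odd_pattern)
    for (block in seq_len(cfg$blocksPerRun)) {
      task <- pattern[block]
      take <- task_cursor[task] + seq_len(cfg$trialsPerBlock)
      task_cursor[task] <- task_cursor[task] + cfg$trialsPerBlock
      blk <- seqs[[task]][take, , drop = FALSE]
      isi <- solveIsiSchedule(cfg$trialsPerBlock, cfg$isiMenuS, cfg$isiTargetS)
      block_onset <- cfg$fixationStartS + (block - 1L) * cfg$blockTotalS
      onset <- block_onset + cfg$instructionS +
        cumsum(c(0, (cfg$imageDurationS + isi)[-cfg$trialsPerBlock]))
      ri <- ri + 1L
      rows[[ri]] <- data.frame(run = run, block = block, task = task,
                               trial = seq_len(cfg$trialsPerBlock),
                               blk[, c("image_id", "category", "quality",
                                       "repetition")],
                               onset_s = onset,
                               duration_s = cfg$imageDurationS, isi_s = isi,
                               stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Generate the counterbalanced event-related design
#'
#' Builds the full trial table: per task, \code{imagesPerCell} unique images
#' in each of the nine category x quality cells, each presented
#' \code{presentationsPerImage} times with a minimum repetition lag enforced
#' by randomized backtracking; task block order follows QA-CC-CC-QA on odd
#' runs and CC-QA-QA-CC on even runs; every block's instruction period, image
#' presentations and exact-sum ISI schedule fill the block duration exactly.
#'
#' @param config a \code{\link{designConfig}} list.
#' @return a \code{\linkS4class{StimulusDesign}}.
#' @examples
#' d <- generateDesign(designConfig(nParticipants = 1, seed = 7))
#' nrow(trialTable(d))  # 2 tasks x 288 trials
#' @export
generateDesign <- function(config = designConfig()) {
  stopifnot(inherits(config, "DesignConfig"))
  ids <- sprintf("sub%02d", seq_len(config$nParticipants))
  trials <- withSeed(config$seed, {
    if (config$sharedOrder) {
      one <- .participantTrials(config)
      do.call(rbind, lapply(ids, function(p)
        cbind(participant = p, one, stringsAsFactors = FALSE)))
    } else {
      do.call(rbind, lapply(ids, function(p)
        cbind(participant = p, .participantTrials(config),
              stringsAsFactors = FALSE)))
    }
  })
  rownames(trials) <- NULL
  new("StimulusDesign", trials = trials[, .TRIAL_COLUMNS], config = unclass(config))
}

#' Bin a mean opinion score into a quality level
#'
#' Scores below 35 are low quality, above 70 high quality, and the closed
#' interval [35, 70] neutral (both boundaries map to neutral).
#'
#' @param mos numeric vector of mean opinion scores on the 0-100 scale.
#' @return character vector of quality levels.
#' @examples
#' binQualityByMos(c(34.9, 35, 70, 70.1))
#' @export
binQualityByMos <- function(mos) {
  if (any(!is.finite(mos)) || any(mos < 0) || any(mos > 100))
    stop("mean opinion scores must lie in [0, 100]")
  ifelse(mos < 35, "low", ifelse(mos > 70, "high", "neutral"))
}
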