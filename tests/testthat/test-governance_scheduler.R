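# Direct scheduler-level tests on virtual time. Requests are submitted
# with distinct study UIDs; dispatch is exercised without performing moves.

sched_rig <- function(projects, windows = list(open_window()),
                      max_concurrent = 100L, start = T0,
                      usage_fn = function(pid) 0) {
  cfg <- test_config(projects = projects, windows = windows,
                     max_concurrent = max_concurrent)
  clk <- new_clock(start)
  s <- new_scheduler(cfg, new_audit_log(tempfile(fileext = ".tsv")), clk,
                     usage_fn = usage_fn)
  list(cfg = cfg, s = s, clk = clk)
}

submit_n <- function(rig, pid, n, tag = pid) {
  for (i in seq_len(n))
    submit_request(rig$s, rig$cfg$projects[[pid]],
                   rig$cfg$projects[[pid]]$members[1],
                   rig$cfg$endpoints[[1]],
                   list(study_instance_uid = sprintf("1.2.3.%s.%d", tag, i),
                        accession_number = sprintf("AN-%s-%d", tag, i),
                        canonical_mrn = rig$cfg$projects[[pid]]$allowlist[1]))
}

three_projects <- list(
  list(id = "PA", members = "ua", allowlist = "11111111"),
  list(id = "PB", members = "ub", allowlist = "22222222"),
  list(id = "PC", members = "uc", allowlist = "33333333"))

test_that("round-robin serves queues [A1,A2],[B1],[C1,C2] as A1,B1,C1,A2,C2", {
  rig <- sched_rig(three_projects)
  submit_n(rig, "PA", 2); submit_n(rig, "PB", 1); submit_n(rig, "PC", 2)
  got <- character(0)
  repeat {
    r <- next_dispatch(rig$s)
    if (is.null(r)) break
    got <- c(got, r$study_ref$study_instance_uid)
  }
  # hand step-through: cursor starts at PA, advances past each chosen project
  expect_equal(got, c("1.2.3.PA.1", "1.2.3.PB.1", "1.2.3.PC.1",
                      "1.2.3.PA.2", "1.2.3.PC.2"))
})

test_that("a 2/minute rate admits two at t=0 and the third only after 60 s", {
  rig <- sched_rig(three_projects[1],
                   windows = list(open_window(rate_count = 2L)))
  submit_n(rig, "PA", 3)
  expect_false(is.null(next_dispatch(rig$s)))
  expect_false(is.null(next_dispatch(rig$s)))
  expect_null(next_dispatch(rig$s))
  clock_advance(rig$clk, 59)
  expect_null(next_dispatch(rig$s))
  clock_advance(rig$clk, 1)   # t = +60 s: the t=0 dispatches leave the window
  expect_false(is.null(next_dispatch(rig$s)))
})

test_that("a rate_count 0 window blocks dispatch entirely", {
  rig <- sched_rig(three_projects[1],
                   windows = list(open_window(rate_count = 0L)))
  submit_n(rig, "PA", 2)
  expect_null(next_dispatch(rig$s))
})

test_that("no dispatch outside all windows; start boundary is inclusive", {
  # weekend-only window, 60/hour
  wk <- list(open_window(rate_count = 60L, rate_period = "hour",
                         days = c("Sat", "Sun")))
  pol <- test_config(windows = wk)$policies$HOSP
  sat3 <- as.POSIXct("2013-06-08 03:00:00", tz = "UTC")
  wed12 <- as.POSIXct("2013-06-05 12:00:00", tz = "UTC")
  w <- current_rate(pol, sat3)
  expect_equal(w$rate_count, 60L)
  expect_equal(w$rate_period, "hour")
  expect_identical(current_rate(pol, wed12), "blocked")
  # Monday 22:00-24:00 window, probed exactly at 22:00
  mon <- test_config(windows = list(open_window(
    days = "Mon", start = 1320L, end = 1440L)))$policies$HOSP
  at2200 <- as.POSIXct("2013-06-03 22:00:00", tz = "UTC")
  expect_equal(current_rate(mon, at2200)$start, 1320L)
  expect_identical(current_rate(mon, at2200 - 1), "blocked")

  rig <- sched_rig(three_projects[1], windows = wk, start = wed12)
  submit_n(rig, "PA", 1)
  expect_null(next_dispatch(rig$s))
})

test_that("max_concurrent caps active moves; zero disables retrieval", {
  rig <- sched_rig(three_projects[1], max_concurrent = 2L)
  submit_n(rig, "PA", 5)
  r1 <- next_dispatch(rig$s); r2 <- next_dispatch(rig$s)
  expect_null(next_dispatch(rig$s))
  transition(rig$s, r1, "COMPLETED")
  expect_false(is.null(next_dispatch(rig$s)))

  rig0 <- sched_rig(three_projects[1], max_concurrent = 0L)
  submit_n(rig0, "PA", 3)
  expect_null(next_dispatch(rig0$s))
})

test_that("state transitions are checked and audited", {
  rig <- sched_rig(three_projects[1])
  submit_n(rig, "PA", 2)
  r <- next_dispatch(rig$s)
  done <- transition(rig$s, r, "COMPLETED")
  expect_equal(done$state, "COMPLETED")
  expect_true(done$finished_at >= done$started_at)
  expect_true(done$started_at >= done$submitted_at)

  r2 <- next_dispatch(rig$s)
  expect_error(transition(rig$s, r2, "FAILED"), class = "pb_state_error")
  failed <- transition(rig$s, r2, "FAILED", failure_reason = "move timeout")
  expect_equal(failed$failure_reason, "move timeout")

  # SCHEDULED -> COMPLETED is illegal
  submit_n(rig, "PA", 1, tag = "extra")
  pending <- request_log(rig$s, state = "SCHEDULED")$id[1]
  expect_error(transition(rig$s, pending, "COMPLETED"),
               class = "pb_state_error")
  ev <- audit_query(rig$s$audit)
  expect_equal(sum(ev$action == "RETRIEVE_COMPLETE"), 1)
  expect_equal(sum(ev$action == "RETRIEVE_FAIL"), 1)
})

test_that("duplicate live submissions are refused, resubmission after failure allowed", {
  rig <- sched_rig(three_projects[1])
  submit_n(rig, "PA", 1)
  expect_error(submit_n(rig, "PA", 1), class = "pb_duplicate_error")
  r <- next_dispatch(rig$s)
  transition(rig$s, r, "FAILED", failure_reason = "move rejected")
  expect_no_error(submit_n(rig, "PA", 1))
})

test_that("submission for an expired project is an authorization error", {
  rig <- sched_rig(list(list(id = "PX", members = "u", allowlist = "44444444",
                             expiration = "2013-01-01")))
  expect_error(submit_n(rig, "PX", 1), class = "pb_authorization_error")
  expect_equal(nrow(audit_query(rig$s$audit, action = "ACCESS_DENIED")), 1)
})

test_that("queued requests of a project that expires are failed at dispatch, never sent", {
  rig <- sched_rig(list(list(id = "PX", members = "u", allowlist = "44444444",
                             expiration = "2013-06-03")))
  submit_n(rig, "PX", 2)
  clock_advance(rig$clk, 2 * 86400)  # past the inclusive expiration day
  expect_null(next_dispatch(rig$s))
  lg <- request_log(rig$s)
  expect_true(all(lg$state == "FAILED"))
  expect_equal(nrow(audit_query(rig$s$audit, action = "ACCESS_DENIED")), 2)
})

test_that("fairness: equal queues drain with prefix imbalance at most 1", {
  for (k in c(2, 3, 5)) {
    projects <- lapply(seq_len(k), function(i)
      list(id = sprintf("Q%02d", i), members = "u",
           allowlist = sprintf("%08d", i)))
    rig <- sched_rig(projects)
    for (p in projects) submit_n(rig, p$id, 6)
    counts <- stats::setNames(integer(k), vapply(projects, `[[`, "", "id"))
    repeat {
      r <- next_dispatch(rig$s)
      if (is.null(r)) break
      counts[r$project_id] <- counts[r$project_id] + 1L
      expect_lte(max(counts) - min(counts), 1)
    }
    expect_true(all(counts == 6L))
  }
})

test_that("liveness: an eligible queued request is always dispatched", {
  set.seed(11)
  rig <- sched_rig(three_projects, windows = list(open_window(rate_count = 5L)),
                   max_concurrent = 3L)
  for (i in 1:100) {
    pid <- sample(c("PA", "PB", "PC"), 1)
    try(submit_n(rig, pid, 1, tag = paste0(pid, i)), silent = TRUE)
    r <- next_dispatch(rig$s)
    if (!is.null(r) && runif(1) < 0.8)
      transition(rig$s, r, "COMPLETED")
    clock_advance(rig$clk, sample(0:30, 1))
  }
  # settle in-flight moves, then drain: with an open window and tokens
  # refilling, everything left in the queues completes
  for (id in request_log(rig$s, state = "PROCESSING")$id)
    transition(rig$s, id, "COMPLETED")
  guard <- 0L
  while (!all(vapply(rig$s$queues, length, 0L) == 0) && guard < 10000L) {
    r <- next_dispatch(rig$s)
    if (is.null(r)) {
      clock_advance(rig$clk, 10)
      guard <- guard + 1L
    } else {
      transition(rig$s, r, "COMPLETED")
    }
  }
  expect_lt(guard, 10000L)
  expect_true(all(request_log(rig$s)$state %in% c("COMPLETED", "FAILED")))
  expect_equal(sum(request_log(rig$s)$state == "FAILED"), 0)
})
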