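ts <- function(x) as.POSIXct(x, tz = "UTC")

make_log <- function(times, receiver = "R1", tag = "T1") {
  data.frame(timestamp = ts(times), tag_id = tag, receiver_id = receiver,
             stringsAsFactors = FALSE)
}

test_that("read_detections parses, sorts and deduplicates", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,receiver,transmitter",
               "2020-01-01 10:00:30,R1,T1",
               "2020-01-01 10:00:00,R1,T1",
               "01/01/2020 09:59:00,R2,T2",
               "2020-01-01 10:00:00,R1,T1"), f)
  expect_message(d <- read_detections(f), "1 duplicate")
  expect_equal(nrow(d), 3)
  expect_equal(attr(d, "n_duplicates"), 1L)
  expect_false(is.unsorted(d$timestamp))
  expect_equal(d$receiver_id[1], "R2") # slash-format timestamp parsed as UTC

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,receiver,transmitter", "not-a-time,R1,T1"), bad)
  expect_error(read_detections(bad), "unparsable timestamp")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("timestamp,receiver,transmitter", empty)
  expect_warning(e <- read_detections(empty), "empty")
  expect_equal(nrow(e), 0)
})

test_that("false-detection screen follows the interval-ratio rule", {
  # burst of 10 pings 60 s apart: nothing isolated, nothing flagged
  burst <- make_log(ts("2020-01-01 10:00:00") + 60 * (0:9))
  res <- filter_false_detections(burst)
  expect_equal(nrow(res$flagged), 0)
  expect_equal(nrow(res$kept), 10)

  # lone ping 13 h from a two-ping cluster whose single interval is long:
  # stream has zero short intervals, every detection is isolated -> flagged
  lone <- make_log(c("2020-01-01 00:00:00", "2020-01-01 13:00:00",
                     "2020-01-02 02:30:00"))
  res <- filter_false_detections(lone)
  expect_equal(nrow(res$flagged), 3)

  # 50 short-interval detections plus one ping 13 h away: the stream's
  # short:long ratio >= 1 protects the isolated ping
  protected <- make_log(c(ts("2020-01-01 00:00:00") + 60 * (0:49),
                          ts("2020-01-01 00:49:00") + 13 * 3600))
  res <- filter_false_detections(protected)
  expect_equal(nrow(res$flagged), 0)

  # streams are (tag, receiver)-scoped: same pattern on another receiver
  # is judged independently
  mixed <- rbind(burst,
                 make_log("2020-01-03 10:00:00", receiver = "R9"))
  res <- filter_false_detections(mixed)
  expect_equal(res$flagged$receiver_id, "R9")
})

test_that("screen output partitions the input and is idempotent", {
  for (seed in 1:5) {
    log <- random_log(80, seed = seed)
    res <- filter_false_detections(log)
    expect_equal(nrow(res$kept) + nrow(res$flagged), nrow(log))
    expect_equal(nrow(merge(res$kept, res$flagged)), 0)
    again <- filter_false_detections(res$kept)
    expect_equal(nrow(again$flagged), 0)
  }
})

test_that("resident events follow the stated opening/closing rules", {
  # two detections 10 min apart: one event
  ev <- detect_resident_events(make_log(c("2020-01-01 10:00:00",
                                          "2020-01-01 10:10:00")))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_detections, 2L)
  expect_equal(ev$duration_min, 10)

  # single detection: no event
  ev <- detect_resident_events(make_log("2020-01-01 10:00:00"))
  expect_equal(nrow(ev), 0)

  # two detections at another receiver close the open event at its last
  # detection; the pair opens the next event
  log <- rbind(make_log(c("2020-01-01 10:00:00", "2020-01-01 10:10:00")),
               make_log(c("2020-01-01 10:15:00", "2020-01-01 10:20:00"),
                        receiver = "R2"),
               make_log("2020-01-01 10:25:00"))
  ev <- detect_resident_events(log)
  expect_equal(ev$receiver_id, c("R1", "R2"))
  expect_equal(ev$end[1], ts("2020-01-01 10:10:00"))
  expect_equal(ev$start[2], ts("2020-01-01 10:15:00"))
  expect_equal(ev$end[2], ts("2020-01-01 10:20:00"))

  # an intervening single detection elsewhere does not close the event
  log <- rbind(make_log(c("2020-01-01 10:00:00", "2020-01-01 10:10:00")),
               make_log("2020-01-01 10:15:00", receiver = "R2"),
               make_log("2020-01-01 10:30:00"))
  ev <- detect_resident_events(log)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_detections, 3L)
  expect_equal(ev$end[1], ts("2020-01-01 10:30:00"))
})

test_that("resident events match the brute-force oracle on random logs", {
  for (seed in 1:12) {
    log <- random_log(sample(c(40, 120, 200), 1), n_receivers = 3,
                      seed = seed)
    got <- detect_resident_events(log)
    want <- oracle_resident_events(log)
    expect_equal(got[c("tag_id", "receiver_id", "start", "end",
                       "n_detections")],
                 want, info = paste("seed", seed))
    # events are disjoint per (tag, receiver) and all have >= 2 members
    expect_true(all(got$n_detections >= 2))
    for (k in unique(paste(got$tag_id, got$receiver_id))) {
      e <- got[paste(got$tag_id, got$receiver_id) == k, ]
      if (nrow(e) > 1) {
        expect_true(all(as.numeric(e$start[-1]) >
                          as.numeric(e$end[-nrow(e)])))
      }
    }
  }
})

test_that("residency index reproduces printed per-individual values", {
  expect_equal(residency_index(92, 115), 80)
  expect_equal(round_half_up(residency_index(61, 107)), 57)
  expect_equal(residency_index(7, 7), 100)
  # scale-free in the day counts
  expect_equal(residency_index(3 * 61, 3 * 107), residency_index(61, 107))
  expect_error(residency_index(5, 0), "tracking_days")
  expect_error(residency_index(9, 8), "exceed")
})

test_that("summarize_tracking computes spans, day counts and RI", {
  tags <- data.frame(tag_id = c("T1", "T2"), manta_id = c("M1", "M2"),
                     sex = "F", maturity = "adult",
                     deploy_date = as.Date("2019-12-01"))
  dets <- rbind(
    make_log(c("2019-12-02 23:00:00", "2019-12-03 01:00:00",
               "2019-12-05 09:00:00"), tag = "T1"),
    make_log("2019-12-04 12:00:00", tag = "T2"))
  s <- summarize_tracking(dets, tags, download_date = "2019-12-10")
  t1 <- s[s$tag_id == "T1", ]
  expect_equal(t1$detection_days, 3)
  expect_equal(t1$tracking_days, 3) # ceil(2.417 days)
  expect_equal(t1$total_time_days, 9)
  expect_equal(t1$ri_percent, 100)
  t2 <- s[s$tag_id == "T2", ]
  expect_equal(t2$tracking_days, 1) # same-day span counts as one day
  expect_equal(t2$ri_percent, 100)
  # calendar convention differs when a span crosses midnight
  s2 <- summarize_tracking(dets, tags, "2019-12-10", span = "calendar")
  expect_equal(s2$tracking_days[s2$tag_id == "T1"], 4)
  # tags with no detections are excluded with a message
  tags3 <- rbind(tags, data.frame(tag_id = "T3", manta_id = "M3", sex = "M",
                                  maturity = "juvenile",
                                  deploy_date = as.Date("2019-12-01")))
  expect_message(s3 <- summarize_tracking(dets, tags3, "2019-12-10"),
                 "no detections")
  expect_equal(nrow(s3), 2)
  expect_error(summarize_tracking(make_log("2019-12-02 10:00:00",
                                           tag = "TX"),
                                  tags, "2019-12-10"), "without metadata")
})

test_that("diel distribution sums to 100 and splits day/night", {
  noon <- make_log(rep("2020-01-01 12:00:00", 5))
  d <- diel_distribution(noon)
  expect_equal(d$day_night$percent[d$day_night$period == "day"], 100)
  expect_equal(sum(d$by_hour$percent), 100)

  uniform <- make_log(sprintf("2020-01-01 %02d:30:00", 0:23))
  d <- diel_distribution(uniform)
  expect_equal(d$by_hour$percent, rep(100 / 24, 24))

  # the synthetic world is day-weighted through diel surface warming
  b <- cached_fixture(1, "small")
  d <- diel_distribution(b$detections)
  expect_gt(d$day_night$percent[d$day_night$period == "day"],
            d$day_night$percent[d$day_night$period == "night"])
})

test_that("site shares recount detections and reject unknown receivers", {
  recv <- data.frame(receiver_id = c("R1", "R2"),
                     site_name = c("Alley", "Reef"))
  log <- rbind(make_log(sprintf("2020-01-01 10:%02d:00", 0:5)),
               make_log(sprintf("2020-01-01 11:%02d:00", 0:1),
                        receiver = "R2"))
  s <- site_share(log, recv)
  expect_equal(sum(s$percent), 100)
  expect_equal(s$percent[s$site == "Alley"], 75)
  expect_equal(s$percent[s$site == "Reef"], 25)
  expect_error(site_share(make_log("2020-01-01 10:00:00", receiver = "RX"),
                          recv), "RX")
  # recount oracle on the synthetic fixture
  b <- cached_fixture(1, "small")
  s <- site_share(b$detections, b$receivers)
  tab <- table(b$detections$receiver_id)
  site <- b$receivers$site_name[match(names(tab), b$receivers$receiver_id)]
  expect_equal(s$n[match(site, s$site)], as.integer(tab))
})
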