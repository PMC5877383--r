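test_that("vehicle kinematics follow the fixed 12 cm / 45 degree quanta", {
  s <- vehicle_state(0, 0, heading = 90)
  f <- step_vehicle(s, "forward")
  expect_equal(c(f$x, f$y), c(0, 12), tolerance = 1e-12)
  expect_equal(f$heading, 90)
  r <- step_vehicle(s, "cw")
  expect_equal(r$heading, 45)
  expect_equal(step_vehicle(s, "ccw")$heading, 135)
  st <- step_vehicle(s, "stop")
  expect_equal(c(st$x, st$y, st$heading), c(0, 0, 90))
  expect_true(st$stopped)
})

test_that("k forward plus k backward commands return to the start", {
  s <- vehicle_state(3, 4, heading = 45)
  for (i in 1:5) s <- step_vehicle(s, "forward")
  for (i in 1:5) s <- step_vehicle(s, "backward")
  expect_equal(c(s$x, s$y), c(3, 4), tolerance = 1e-9)
})

test_that("paradigm 2 issues a command only on two consecutive equal windows", {
  cfg <- paradigm_config(2)
  one <- run_paradigm(c("MF", "MF"), cfg)
  expect_equal(sum(one$command_log$command != "stop"), 1)
  expect_equal(one$command_log$command[2], "forward")
  none <- run_paradigm(c("MF", "WE"), cfg)
  expect_equal(sum(none$command_log$command != "stop"), 0)
  # a command consumes its confirming pair: MF,MF,MF is one command
  three <- run_paradigm(c("MF", "MF", "MF"), cfg)
  expect_equal(sum(three$command_log$command != "stop"), 1)
})

test_that("paradigm 2 rest maps to backward and unknown labels error", {
  cfg <- paradigm_config(2)
  res <- run_paradigm(c("REST", "REST"), cfg)
  expect_equal(res$command_log$command[2], "backward")
  expect_error(run_paradigm(c("MF", "JUMP"), cfg), "unknown label")
})

test_that("paradigm 3 moves only when both channels agree", {
  cfg <- paradigm_config(3)
  res <- run_paradigm(cbind(c("MF", "MF", "WE"), c("MF", "WE", "WE")), cfg)
  expect_equal(res$command_log$command, c("forward", "stop", "cw"))
  stuck <- run_paradigm(cbind(rep("MF", 5), rep("WE", 5)), cfg)
  expect_equal(stuck$final_state$x, 0)
  expect_equal(stuck$final_state$y, 0)
})

test_that("paradigm 4 state machine toggles only after a motion was executed", {
  cfg <- paradigm_config(4)
  res <- run_paradigm(c("REST", "WF", "REST", "WF"), cfg)
  log <- res$command_log
  expect_equal(log$event[1], "switch_refused")   # no motion yet in this mode
  expect_equal(log$command[2], "forward")        # straight mode: WF = forward
  expect_equal(log$event[3], "mode_switch")
  expect_equal(log$command[4], "ccw")            # rotation mode: WF = ccw
  expect_equal(res$final_state$mode, "rotation")
})

test_that("paradigm 4 mode parity: an even number of switches restores the mode", {
  cfg <- paradigm_config(4)
  stream <- c("WF", "REST", "WE", "REST", "WF", "WE")
  res <- run_paradigm(stream, cfg)
  switches <- sum(res$command_log$event == "mode_switch")
  expect_equal(switches %% 2, 0)
  expect_equal(res$final_state$mode, "straight")
  expect_equal(res$command_log$command[6], "backward")  # MF stops, WE backward
})

test_that("fisting stops the vehicle in paradigm 4", {
  cfg <- paradigm_config(4)
  res <- run_paradigm(c("WF", "MF", "WF"), cfg)
  expect_equal(res$command_log$command, c("forward", "stop", "forward"))
})

test_that("obstacles convert a translation into a logged avoidance stop", {
  cfg <- paradigm_config(3, map = map_config(obstacles = list(c(-5, 5, 6, 20))))
  res <- run_paradigm(cbind(c("MF", "MF"), c("MF", "MF")), cfg)
  expect_equal(res$collisions, 2L)
  expect_equal(res$final_state$y, 0)
  expect_true(all(res$command_log$event == "collision_avoided"))
})

test_that("ideal route time matches closed-form kinematics", {
  expect_equal(ideal_route_time(map_config(40, 2)), 320 / 12 + 8 * 2,
               tolerance = 1e-12)
  expect_equal(ideal_route_time(path_cm = 40, turns_deg = 0), 40 / 12,
               tolerance = 1e-12)
  expect_equal(ideal_route_time(path_cm = 120), 10)  # zero rotation limit
  expect_error(ideal_route_time(map_config(40, 2), linear_speed_cm_s = 0),
               "positive")
})

test_that("a full two-loop session can never beat the kinematic lower bound", {
  # 4 x 12 cm per side overshoots the 40 cm side; 2 x 45 degrees per corner
  side <- c(rep("MF", 4), rep("WE", 2))
  stream <- rep(side, 8)                       # 8 sides = 2 loops
  cfg <- paradigm_config(3)
  res <- run_paradigm(cbind(stream, stream), cfg)
  expect_gte(res$travel_time_s, ideal_route_time(map_config(40, 2)))
})

test_that("recognition rates follow their paradigm definitions", {
  expect_equal(recognition_rate(rep("MF", 10), rep("MF", 10), paradigm = 2), 100)
  pred <- rep("MF", 10); pred[4] <- "WE"
  expect_equal(recognition_rate(pred, rep("MF", 10), paradigm = 2), 90)
  ch <- cbind(rep("MF", 10), rep("WE", 10))
  expect_equal(recognition_rate(ch, paradigm = 3), 0)
  agree <- cbind(rep("MF", 10), c(rep("MF", 9), "WE"))
  expect_equal(recognition_rate(agree, paradigm = 3), 90)
  expect_true(is.na(recognition_rate(rep("MF", 5), paradigm = 4)))
  expect_error(recognition_rate(pred, rep("MF", 9), paradigm = 2),
               "length mismatch")
})
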