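# Small scene builders shared across tests.

small_scene <- function(behaviors = "still_sit", sleeves = "Long",
                        n_frames = 60, seed = 1, frame_shape = c(200, 150),
                        noise = list(), skin = 34.5, clothes = 33.0,
                        background = 25.0, ...) {
  persons <- Map(function(b, s) scene_person(b, s, skin_temperature = skin,
                                             clothes_temperature = clothes),
                 behaviors, sleeves)
  names(persons) <- NULL
  generate_scene(scene_script(persons = persons,
                              background_temperature = background,
                              frame_shape = frame_shape,
                              n_frames = n_frames, seed = seed,
                              noise = noise), ...)
}

full_kp <- function(score = 0.9) {
  data.frame(
    name = c("nose", "left_shoulder", "right_shoulder", "left_elbow",
             "right_elbow", "left_wrist", "right_wrist"),
    u = c(50, 30, 70, 25, 75, 20, 80),
    v = c(10, 25, 25, 45, 45, 65, 65),
    score = score, stringsAsFactors = FALSE)
}

# Tiny pre-trained classifier reused by pipeline-level tests (trained once
# per session on a small synthetic dataset).
tiny_classifier <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- fit_activity_classifier(
        generate_activity_dataset(5, seed = 99), seed = 0)
    cache
  }
})
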