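Package: reachclone
Title: Synthetic Arm-Reaching Motion Cloning and Shoulder-Elbow Synergy Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying inter-joint synergy in center-out-center arm
    reaching. Provides a 7-degree-of-freedom kinematic arm model with
    redundancy-resolved inverse kinematics, a reinforcement-learning reaching
    environment trained with soft actor-critic to clone human-like reaching
    motion, a surrogate-subject generator emulating multi-subject motion-capture
    sessions, a CNN-LSTM decoder that predicts elbow joint angles from shoulder
    joint angles, and evaluation utilities (Pearson correlation, RMSE in
    degrees, forward-kinematic target-reaching error) together with end-to-end
    experiment scenarios for synthetic-only training and hybrid data
    augmentation with cross-subject testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
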