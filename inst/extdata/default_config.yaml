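# Default model configuration. Units: SI (kg, m, s, rad, N).
# Every field is optional; omitted fields use these values.
arm:
  mass: [1.79, 1.02, 0.77]          # link masses; distal link includes a 0.39 kg cup
  length: [0.24, 0.22, 0.17]
  com_offset: [0.10, 0.09, 0.08]    # proximal joint -> link centre of mass
  inertia: [0.0300, 0.0134, 0.0073] # about each link's centre of mass
  gravity: 9.81
gains:
  stiffness:                         # K, N m/rad (rows: shoulder, elbow, wrist)
    - [20, 5, 0]
    - [5, 10, 0]
    - [0, 0, 5]
  viscosity:                         # D, N m s/rad
    - [1.5, 0.5, 0]
    - [0.5, 1.0, 0]
    - [0, 0, 0.4]
  damper: [0, 0]                     # skyhook virtual damper diagonal, N s/m
  # Desired posture (rad) = (-80, 90, -5) deg. NOTE: a modelling choice, not
  # a measured value — upper arm near vertical, forearm 10 deg above
  # horizontal, hand segment 5 deg down from the forearm.
  posture: [-1.3962634015954636, 1.5707963267948966, -0.0872664625997165]
oscillation:
  amplitude: 0.03                    # m
  frequency: 1.09                    # Hz
  phase: 0
plan:
  dt: 0.01                           # s
  duration: 100                      # s
  steady_window: [30, 90]            # s
  controller: active
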