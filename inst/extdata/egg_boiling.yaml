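module_id: egg_boiling
name: Simulated egg-boiling task
frame_period_ms: 5.0
smoothing_window: 5
class_vocabulary:
- table
- hand
- pot_empty
- pot_with_water
- pot_with_egg
- pot_upside_down
- pitcher
- pitcher_lifted
- wrong_object_lifted
- water_spilled
- egg
- egg_dropped
- egg_in_hand
- cooker_off
- cooker_on
- cooker_lid_open
- cooker_lid_closed
- lid_misaligned
- wrong_button
- sponge
steps:
- step_id: place_pot
  index: 0
  instruction_text: Place the pot on the cooker.
  time_limit_s: 30.0
  completion_condition:
    required_present: [pot_empty]
    required_absent: [pot_upside_down]
    spatial_predicates:
    - {relation: contains, subject: pot_empty, object: cooker_off}
    dwell_frames: 5
  error_conditions:
  - condition:
      required_present: [pot_upside_down]
      required_absent: []
      spatial_predicates: []
      dwell_frames: 2
    corrective_instruction: The pot is upside down. Turn it over and place it
      on the cooker.
  cue_schedule:
  - {level: 1, stall_timeout_s: 15.0, text: Start by placing the pot on the cooker.}
  - {level: 2, stall_timeout_s: 30.0, text: (points at the pot)}
  - {level: 3, stall_timeout_s: 45.0, text: Pick up the pot and put it on the
      cooker now.}
  - {level: 4, stall_timeout_s: 60.0, text: (guides the participant's hand to
      the pot)}
  - {level: 5, stall_timeout_s: 75.0, text: (assessor places the pot on the cooker)}
- step_id: fetch_pitcher
  index: 1
  instruction_text: Pick up the water pitcher.
  time_limit_s: 30.0
  completion_condition:
    required_present: [pitcher_lifted]
    required_absent: []
    spatial_predicates: []
    dwell_frames: 5
  error_conditions:
  - condition:
      required_present: [wrong_object_lifted]
      required_absent: []
      spatial_predicates: []
      dwell_frames: 2
    corrective_instruction: That is not the pitcher. Put it down and pick up
      the water pitcher.
  cue_schedule:
  - {level: 1, stall_timeout_s: 15.0, text: Next, pick up the water pitcher.}
  - {level: 2, stall_timeout_s: 30.0, text: (points at the pitcher)}
  - {level: 3, stall_timeout_s: 45.0, text: Reach for the pitcher on your left
      and pick it up.}
  - {level: 4, stall_timeout_s: 60.0, text: (guides the participant's hand to
      the pitcher)}
  - {level: 5, stall_timeout_s: 75.0, text: (assessor picks up the pitcher)}
- step_id: pour_water
  index: 2
  instruction_text: Pour water from the pitcher into the pot.
  time_limit_s: 30.0
  completion_condition:
    required_present: [pot_with_water]
    required_absent: [pot_empty]
    spatial_predicates: []
    dwell_frames: 5
  error_conditions:
  - condition:
      required_present: [water_spilled]
      required_absent: []
      spatial_predicates: []
      dwell_frames: 2
    corrective_instruction: Water has spilled. Aim the pitcher over the pot
      and pour again.
  cue_schedule:
  - {level: 1, stall_timeout_s: 15.0, text: Pour the water into the pot.}
  - {level: 2, stall_timeout_s: 30.0, text: (mimes pouring over the pot)}
  - {level: 3, stall_timeout_s: 45.0, text: Tilt the pitcher over the pot until
      water flows in.}
  - {level: 4, stall_timeout_s: 60.0, text: (supports the pitcher while the
      participant pours)}
  - {level: 5, stall_timeout_s: 75.0, text: (assessor pours the water)}
- step_id: place_egg
  index: 3
  instruction_text: Place the egg into the pot.
  time_limit_s: 30.0
  completion_condition:
    required_present: [pot_with_egg]
    required_absent: []
    spatial_predicates: []
    dwell_frames: 5
  error_conditions:
  - condition:
      required_present: [egg_dropped]
      required_absent: []
      spatial_predicates: []
      dwell_frames: 2
    corrective_instruction: The egg fell outside the pot. Pick it up and place
      it gently into the pot.
  cue_schedule:
  - {level: 1, stall_timeout_s: 15.0, text: Now place the egg into the pot.}
  - {level: 2, stall_timeout_s: 30.0, text: (points at the egg)}
  - {level: 3, stall_timeout_s: 45.0, text: Pick up the egg and lower it into
      the water.}
  - {level: 4, stall_timeout_s: 60.0, text: (guides the participant's hand with
      the egg)}
  - {level: 5, stall_timeout_s: 75.0, text: (assessor places the egg)}
- step_id: close_lid
  index: 4
  instruction_text: Close the cooker lid.
  time_limit_s: 30.0
  completion_condition:
    required_present: [cooker_lid_closed]
    required_absent: [cooker_lid_open]
    spatial_predicates: []
    dwell_frames: 5
  error_conditions:
  - condition:
      required_present: [lid_misaligned]
      required_absent: []
      spatial_predicates: []
      dwell_frames: 2
    corrective_instruction: The lid is not seated. Lift it and close it until
      it sits flat.
  cue_schedule:
  - {level: 1, stall_timeout_s: 15.0, text: Close the lid of the cooker.}
  - {level: 2, stall_timeout_s: 30.0, text: (points at the lid)}
  - {level: 3, stall_timeout_s: 45.0, text: Take the lid and press it down onto
      the cooker.}
  - {level: 4, stall_timeout_s: 60.0, text: (guides the participant's hand to
      the lid)}
  - {level: 5, stall_timeout_s: 75.0, text: (assessor closes the lid)}
- step_id: press_switch
  index: 5
  instruction_text: Press the cook switch to start cooking.
  time_limit_s: 30.0
  completion_condition:
    required_present: [cooker_on]
    required_absent: [cooker_off]
    spatial_predicates: []
    dwell_frames: 5
  error_conditions:
  - condition:
      required_present: [wrong_button]
      required_absent: []
      spatial_predicates: []
      dwell_frames: 2
    corrective_instruction: That is the wrong button. Press the cook switch at
      the front of the cooker.
  cue_schedule:
  - {level: 1, stall_timeout_s: 15.0, text: Finally, press the cook switch.}
  - {level: 2, stall_timeout_s: 30.0, text: (points at the switch)}
  - {level: 3, stall_timeout_s: 45.0, text: Press the switch at the front of
      the cooker down.}
  - {level: 4, stall_timeout_s: 60.0, text: (guides the participant's finger
      to the switch)}
  - {level: 5, stall_timeout_s: 75.0, text: (assessor presses the switch)}
efpt_components:
- {component_id: locate_cookware, member_step_ids: [place_pot]}
- {component_id: fetch_water, member_step_ids: [fetch_pitcher]}
- {component_id: fill_pot, member_step_ids: [pour_water, place_egg]}
- {component_id: close_lid, member_step_ids: [close_lid]}
- {component_id: start_cooking, member_step_ids: [press_switch]}
completion_rules:
  error_downgrades: true
  overtime_downgrades: true
  zero_credit_cue_level: 5
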