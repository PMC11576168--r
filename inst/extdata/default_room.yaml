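width: 9
height: 9
n_optional_goals: 3
required_goal_pos:
- 9
- 9
hazard_positions:
- - 2
  - 1
reward_optional: 1.0
reward_required: 10.0
reward_hazard: -5.0
max_steps_per_episode: 500
include_optional: yes
include_hazards: yes
start_pos:
- 1
- 1
start_heading: E
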