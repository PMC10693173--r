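# Example personal-preference record for weekly recommendation generation.
goal_setting: weekly
nature_of_goal: generic_WHO
frequency: weekly
target_goal: Stay medium active for the entire week
target_score: 21
mode: push_notification
delivery_time: "08:00"
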