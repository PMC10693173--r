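variables:
- id: A-2
  description: low-active day
  daily: no
- id: A-3
  description: active day
  daily: no
- id: A-4
  description: medium-active day
  daily: no
- id: A-5
  description: highly-active day
  daily: no
- id: A-6
  description: non-sedentary day (step threshold met)
  daily: no
- id: A-8
  description: daily score below the medium-active target
  daily: no
- id: A-9
  description: daily score at or above the medium-active target
  daily: no
- id: A-10
  description: daily pace needs improvement
  daily: no
- id: A-11
  description: daily pace on target
  daily: no
- id: A-13
  description: next-week step forecast below the weekly goal pace
  daily: no
- id: A-14
  description: 'once a day: keep up the good work'
  daily: yes
- id: A-15
  description: 'once a day: move more today'
  daily: yes
- id: A-16
  description: weekly goal achieved
  daily: no
- id: A-17
  description: weekly goal missed
  daily: no
rules:
- id: R-1
  antecedent: NOT A-6
  consequent: A-15
  scope: daily
  rule_class: activity_level
- id: R-2
  antecedent: A-2 AND A-8
  consequent: A-15
  scope: daily
  rule_class: activity_level
- id: R-3
  antecedent: A-3 AND A-8
  consequent: A-15
  scope: daily
  rule_class: activity_level
- id: R-4
  antecedent: A-4 AND A-9
  consequent: A-14
  scope: daily
  rule_class: activity_level
- id: R-5
  antecedent: A-5 AND A-9
  consequent: A-14
  scope: daily
  rule_class: activity_level
- id: R-6
  antecedent: A-17
  consequent: A-17
  else_consequent: A-16
  scope: weekly
  rule_class: activity_level
- id: R-7
  antecedent: A-13
  consequent: A-13
  scope: weekly
  rule_class: activity_level
- id: R-8
  rule_class: satisfiability
  scope: guard
  antecedent: NOT (A-8 AND A-9) AND NOT (A-9 AND NOT A-6)
  consequent: guard
messages:
  A-13:
    formal: Your step forecast for the coming week is below your goal pace. Plan extra
      activity next week.
    informal: Aim a little higher next week! {emoji}
  A-14:
    formal: You reached the daily activity target today. Keep it up.
    informal: Great job today! {emoji}
  A-15:
    formal: You are below the daily activity target today. Try to move more.
    informal: Time to move a little more! {emoji}
  A-16:
    formal: Congratulations! You reached your weekly goal of {goal} points with {achieved}
      points.
    informal: Well done! {emoji}
  A-17:
    formal: You are {deficit} points behind to reach your weekly goal. Work hard on
      the following week.
    informal: Improve your performance to meet the goal! {emoji}
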