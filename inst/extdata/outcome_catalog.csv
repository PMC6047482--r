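item_id,label,kind
pain_relief,Pain relief,benefit
normal_activities,Improvement in your ability to do normal activities,benefit
sleep,Improvement in sleep,benefit
quality_of_life,Changes in the overall quality of your life,benefit
mood,Changes in mood,benefit
less_medication,Reduction in the need for other pain medication,benefit
side_effects,Side effects (all potential harms),side_effects_aggregate
death,Death,harm
fainting,Fainting,harm
headache,Headache,harm
dizziness,Dizziness,harm
nausea,Nausea or vomiting,harm
drowsiness,Drowsiness or sedation,harm
fatigue,Fatigue or weakness,harm
memory_problems,Memory problems,harm
concentration,Difficulty concentrating,harm
mood_changes,Mood changes (e.g. irritability or depression),harm
suicidal_thoughts,Suicidal thoughts,harm
weight_gain,Weight gain,harm
appetite_change,Changes in appetite,harm
dry_mouth,Dry mouth,harm
constipation,Constipation,harm
stomach_problems,Stomach problems (e.g. pain or indigestion),harm
skin_problems,Skin problems (e.g. dry skin or rash),harm
vision_problems,Blurred or double vision,harm
tremor,Tremor or shaking,harm
balance_problems,Problems with balance or coordination,harm
swelling,Swelling of the hands or feet,harm
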