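raw,canonical,class,region,is_pain
Pain in interphalangeal joints,Upper limb joint pain,symptom,,
Wrist pain,Upper limb joint pain,symptom,,
Elbow pain,Upper limb joint pain,symptom,,
Shoulder pain,Upper limb joint pain,symptom,,
Ankle pain,Joint pain of lower extremity,symptom,,
Knee joint pain,Joint pain of lower extremity,symptom,,
Lower extremity joint pain,Joint pain of lower extremity,symptom,,
Lumbar pain,Lumbosacral pain,symptom,,
Hip pain,Lumbosacral pain,symptom,,
Sacral joint pain,Lumbosacral pain,symptom,,
Pain improvement,Pain reduction,symptom,,
Pain relief,Pain reduction,symptom,,
Difficulty bending,Unfavorable activity,symptom,,
Limb soreness,Limb discomfort,symptom,,
Neck discomfort,Limb discomfort,symptom,,
Burnout,Fatigue,symptom,,
Upper limb joint pain,Upper limb joint pain,symptom,upper_limb,TRUE
Joint pain of lower extremity,Joint pain of lower extremity,symptom,lower_limb,TRUE
Lumbosacral pain,Lumbosacral pain,symptom,lumbosacral,TRUE
Polyarthralgia,Polyarthralgia,symptom,,TRUE
Thready pulse,Thready pulse,symptom,,
Poor sleep,Poor sleep,symptom,,
Thin moss,Thin moss,symptom,,
White moss,White moss,symptom,,
Red tongue,Red tongue,symptom,,
Inflexibility in body movements,Inflexibility in body movements,symptom,,
Taut pulse,Taut pulse,symptom,,
Fatigue,Fatigue,symptom,,
Loose stools,Loose stools,symptom,,
Morning stiffness,Morning stiffness,symptom,,
Physical discomfort,Physical discomfort,symptom,,
Dry mouth,Dry mouth,symptom,,
Deep pulse,Deep pulse,symptom,,
Dry eyes,Dry eyes,symptom,,
Pain reduction,Pain reduction,symptom,,
Unfavorable activity,Unfavorable activity,symptom,,
Limb discomfort,Limb discomfort,symptom,,
Greasy moss,Greasy moss,symptom,,
Dark tongue,Dark tongue,symptom,,
Han Fangji,Fangji,herb,,
Panax notoginseng powder,Sanqi,herb,,
Jinyinhua,Jinyinhua,herb,,
Yiyiren,Yiyiren,herb,,
Wugong,Wugong,herb,,
Qingfengteng,Qingfengteng,herb,,
Chaobaishao,Chaobaishao,herb,,
Tusizi,Tusizi,herb,,
Baizhu,Baizhu,herb,,
Fuzi,Fuzi,herb,,
Guizhi,Guizhi,herb,,
Qianghuo,Qianghuo,herb,,
Tufuling,Tufuling,herb,,
Fangji,Fangji,herb,,
Sangjisheng,Sangjisheng,herb,,
Shuizhi,Shuizhi,herb,,
Huainiuxi,Huainiuxi,herb,,
Duhuo,Duhuo,herb,,
Chuipencao,Chuipencao,herb,,
Xuchangqing,Xuchangqing,herb,,
Rendongteng,Rendongteng,herb,,
Duzhong,Duzhong,herb,,
Huangqi,Huangqi,herb,,
Chuanniuxi,Chuanniuxi,herb,,
Niuxigen,Niuxigen,herb,,
Sanqi,Sanqi,herb,,
Gancao,Gancao,herb,,
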