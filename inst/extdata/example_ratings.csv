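observer_id,group,mode,item01,item02,item03,item04,item05,item06,item07,item08,item09,item10,item11,item12,item13,item14,item15,item16,item17,item18,item19,item20
ex001,forensic_examiner,offline,4,-1,5,3,4,3,5,4,5,4,5,4,0,0,-3,2,0,-4,-4,2
ex002,forensic_examiner,offline,2,-3,1,1,2,3,5,3,3,3,2,5,-1,-3,-1,-1,-5,-5,0,0
sr001,super_recognizer,online,5,5,5,5,5,5,5,5,5,-1,5,5,5,-5,-1,-5,3,-5,-5,5
sr002,super_recognizer,online,5,5,5,2,5,5,5,5,5,5,5,5,5,5,2,2,-5,-5,-5,2
nov001,novice,online,1,-2,1,1,3,-1,3,3,1,-1,5,3,-5,-3,1,-1,-2,-5,-3,-1
nov002,novice,online,4,-3,2,1,2,5,,2,1,2,-1,-1,1,-4,-5,-4,1,-5,-4,3
dnn001,dnn,not_applicable,1.079,0.611,-0.426,1.252,0.952,-0.185,1.031,0.306,1.509,-0.056,0.568,2.556,-0.643,-0.873,-0.467,-0.174,-0.931,0.282,0.684,-0.773
dnn002,dnn,not_applicable,1.488,-0.612,0.435,1.626,0.807,1.027,1.238,0.933,1.81,1.025,1.188,1.159,-0.854,-0.069,-0.698,-1.088,-0.105,0.34,-0.486,-1.689
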