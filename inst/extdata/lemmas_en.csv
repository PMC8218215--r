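form,lemma
quitting,quit
quits,quit
quitted,quit
smoking,smoke
smokes,smoke
smoked,smoke
smokers,smoker
vaping,vape
vapes,vape
vaped,vape
vapers,vaper
juuling,juul
juuls,juul
craving,crave
cravings,crave
craves,crave
craved,crave
addicted,addict
addicts,addict
addictions,addiction
loving,love
loves,love
loved,love
liking,like
likes,like
liked,like
breaks,break
breaking,break
broke,break
broken,break
cigarettes,cigarette
cig,cigarette
cigs,cigarette
ciggies,cigarette
cigars,cigar
patches,patch
gums,gum
stopping,stop
stops,stop
stopped,stop
trying,try
tries,try
tried,try
needs,need
needed,need
needing,need
wants,want
wanted,want
wanting,want
teens,teen
teenager,teen
teenagers,teen
kids,kid
children,child
childs,child
schools,school
shots,shot
effects,effect
risks,risk
lungs,lung
brains,brain
drinking,drink
drinks,drink
drank,drink
beers,beer
wines,wine
coffees,coffee
days,day
withdrawals,withdrawal
helps,help
helped,help
helping,help
going,go
goes,go
went,go
gone,go
feeling,feel
feels,feel
felt,feel
makes,make
made,make
making,make
gets,get
got,get
getting,get
gotten,get
uses,use
used,use
using,use
boosts,boost
boosting,boost
boosted,boost
replaces,replace
replacing,replace
replaced,replace
supplements,supplement
products,product
liquids,liquid
pods,pod
mods,mod
magnets,magnet
ears,ear
buzzing,buzz
safer,safe
safest,safe
harms,harm
harming,harm
harmed,harm
hurts,hurt
hurting,hurt
words,word
thinks,think
thinking,think
thought,think
says,say
said,say
saying,say
knows,know
knowing,know
knew,know
known,know
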