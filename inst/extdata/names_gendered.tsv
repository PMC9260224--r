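mary	female
patricia	female
linda	female
barbara	female
elizabeth	female
jennifer	female
maria	female
susan	female
margaret	female
dorothy	female
lisa	female
nancy	female
karen	female
betty	female
helen	female
sandra	female
donna	female
carol	female
ruth	female
sharon	female
michelle	female
laura	female
sarah	female
kimberly	female
deborah	female
jessica	female
shirley	female
cynthia	female
angela	female
melissa	female
brenda	female
amy	female
anna	female
rebecca	female
virginia	female
kathleen	female
pamela	female
martha	female
debra	female
amanda	female
stephanie	female
carolyn	female
christine	female
marie	female
janet	female
catherine	female
frances	female
ann	female
joyce	female
diane	female
alice	female
julie	female
heather	female
teresa	female
doris	female
gloria	female
evelyn	female
jean	female
cheryl	female
mildred	female
katherine	female
joan	female
ashley	female
judith	female
rose	female
janice	female
kelly	female
nicole	female
judy	female
christina	female
kathy	female
theresa	female
beverly	female
denise	female
tammy	female
irene	female
jane	female
lori	female
rachel	female
marilyn	female
andrea	female
kathryn	female
louise	female
sara	female
anne	female
jacqueline	female
wanda	female
bonnie	female
julia	female
ruby	female
lois	female
tina	female
phyllis	female
norma	female
paula	female
diana	female
annie	female
lillian	female
emily	female
robin	female
rita	female
brigitte	female
chloe	female
zoe	female
amelia	female
harper	female
evie	female
isla	female
freya	female
sophia	female
olivia	female
ava	female
emma	female
mia	female
charlotte	female
grace	female
lily	female
ella	female
hannah	female
abigail	female
james	male
john	male
robert	male
michael	male
william	male
david	male
richard	male
charles	male
joseph	male
thomas	male
christopher	male
daniel	male
paul	male
mark	male
donald	male
george	male
kenneth	male
steven	male
edward	male
brian	male
ronald	male
anthony	male
kevin	male
jason	male
matthew	male
gary	male
timothy	male
jose	male
larry	male
jeffrey	male
frank	male
scott	male
eric	male
stephen	male
andrew	male
raymond	male
gregory	male
joshua	male
jerry	male
dennis	male
walter	male
patrick	male
peter	male
harold	male
douglas	male
henry	male
carl	male
arthur	male
ryan	male
roger	male
joe	male
juan	male
jack	male
albert	male
jonathan	male
justin	male
terry	male
gerald	male
keith	male
samuel	male
willie	male
ralph	male
lawrence	male
nicholas	male
roy	male
benjamin	male
bruce	male
brandon	male
adam	male
harry	male
fred	male
wayne	male
billy	male
steve	male
louis	male
jeremy	male
aaron	male
randy	male
howard	male
eugene	male
carlos	male
russell	male
bobby	male
victor	male
martin	male
ernest	male
phillip	male
todd	male
jesse	male
craig	male
alan	male
shawn	male
clarence	male
sean	male
philip	male
chris	male
johnny	male
earl	male
jimmy	male
antonio	male
oliver	male
noah	male
leo	male
oscar	male
finley	male
ethan	male
lucas	male
mason	male
logan	male
alexander	male
jacob	male
sebastian	male
alex	female
alex	male
taylor	female
taylor	male
jordan	female
jordan	male
casey	female
casey	male
morgan	female
morgan	male
riley	female
riley	male
jamie	female
jamie	male
avery	female
avery	male
quinn	female
quinn	male
cameron	female
cameron	male
skyler	female
skyler	male
rowan	female
rowan	male
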